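# Quasi-steady diastolic state of the baseline control model.
# Frozen from a 2000-s drug-free pre-simulation (adaptive integrator,
# rtol = atol = 1e-5); order matches .state_names.
.baseline_initial_state <- c(
  Vm   = -0.0708710935631451,
  m    = 0.12516610908751,
  h    = 0.693485568945602,
  j    = 0.289310630304278,
  d    = 0.000146936533422847,
  f1   = 0.991546152911867,
  f2   = 0.999961823368144,
  fCa  = 0.998863986834323,
  Xr1  = 3.56972096997872e-05,
  Xr2  = 0.415269294813322,
  Xs   = 0.0399468311973555,
  Xf   = 0.116462729816217,
  q    = 0.800594425722721,
  r    = 0.00688603544126746,
  g    = 0.99999997336973,
  mL   = 0.00485372080376593,
  hL   = 0.12529320450738,
  Nai  = 10.7258473201727,
  Cai  = 1.91404243241352e-05,
  CaSR = 0.0572657745035633
)
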