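# Group contrasts: the ionic-mechanism summaries behind the phenotype and
# drug-response comparisons.

# absolute maxima (scale factor x baseline) for the sampled parameters
.absolute_maxima <- function(df) {
  out <- df[, .sampled_names, drop = FALSE]
  for (nm in .sampled_names) out[[nm]] <- out[[nm]] * .baseline_maxima[[nm]]
  out
}

#' Compare two groups of models by medians
#'
#' For each requested quantity, reports the group medians and the percent
#' difference `100 * (A - B) / B`. Conductance quantities are compared on
#' absolute maxima (scale factor times baseline maximum, i.e. S/F,
#' cm^3/F/s, A/F scales); biomarker quantities on their own units.
#'
#' @param popA,popB data.frames (populations or subsets); non-empty.
#' @param quantities character vector of sampled-parameter and/or biomarker
#'   names; default all 11 sampled maxima.
#' @param test add a Wilcoxon rank-sum p-value per quantity (exploratory
#'   only).
#' @return object of class `group_contrast` (a data.frame): quantity,
#'   median_A, median_B, pct_diff, n_A, n_B.
#' @export
compare_groups <- function(popA, popB, quantities = .sampled_names,
                           test = FALSE) {
  if (!nrow(popA) || !nrow(popB)) stop("empty group in contrast")
  getq <- function(df, q) {
    if (q %in% .sampled_names) .absolute_maxima(df)[[q]] else df[[q]]
  }
  rows <- lapply(quantities, function(q) {
    a <- getq(popA, q); b <- getq(popB, q)
    if (is.null(a) || is.null(b)) stop("quantity not present: ", q)
    ma <- stats::median(a, na.rm = TRUE); mb <- stats::median(b, na.rm = TRUE)
    pct <- if (isTRUE(all.equal(mb, 0)) || mb == 0) NA_real_ else
      100 * (ma - mb) / mb
    out <- data.frame(quantity = q, median_A = ma, median_B = mb,
                      pct_diff = pct, n_A = length(a), n_B = length(b))
    if (test)
      out$p_value <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("group_contrast", "data.frame")
  out
}

#' Contrast control ancestors of symptomatic vs asymptomatic mutants
#'
#' Splits the control population according to the phenotype label its
#' one-to-one mutant descendant received, and contrasts control-genotype
#' biomarkers between the two ancestor groups.
#'
#' @param control the calibrated control `population`.
#' @param mutant_labels named character vector (or labelled mutant
#'   population): label per mutant model id.
#' @param quantities biomarkers to contrast (default rate, Vmax, APD90 and
#'   companions).
#' @return `group_contrast` with A = ancestors of symptomatic, B = ancestors
#'   of asymptomatic.
#' @export
ancestor_contrast <- function(control, mutant_labels,
                              quantities = c("rate", "MDP", "Peak", "APA",
                                             "Vmax", "APD90")) {
  if (inherits(mutant_labels, "population")) {
    if (is.null(mutant_labels$label)) stop("mutant population is unlabelled")
    mutant_labels <- stats::setNames(mutant_labels$label, mutant_labels$id)
  }
  ids <- as.integer(names(mutant_labels))
  if (any(is.na(ids)) || !all(ids %in% control$id))
    stop("broken control-mutant id mapping")
  anc <- as.data.frame(control)[match(ids, control$id), , drop = FALSE]
  A <- anc[mutant_labels == "symptomatic", , drop = FALSE]
  B <- anc[mutant_labels == "asymptomatic", , drop = FALSE]
  if (!nrow(A) || !nrow(B)) stop("empty group in contrast")
  compare_groups(A, B, quantities = quantities)
}

#' Contrast stopped vs beating models of a drug trial at one dose
#'
#' @param trial a [drug_trial()] result.
#' @param pop the population the trial ran on (source of the conductance
#'   scale factors).
#' @param dose_uM the dose to analyse.
#' @param quantities sampled-parameter names (default all 11).
#' @return `group_contrast` with A = stopped (no AP), B = beating.
#' @export
stopped_vs_beating_contrast <- function(trial, pop, dose_uM,
                                        quantities = .sampled_names) {
  stopifnot(inherits(trial, "drug_trial"))
  sub <- trial$per_model[trial$per_model$dose_uM == dose_uM, ]
  if (!nrow(sub)) stop("no trial rows at dose ", dose_uM)
  df <- as.data.frame(pop)
  stopped <- df[df$id %in% sub$id[sub$status == "quiescent"], , drop = FALSE]
  beating <- df[df$id %in% sub$id[sub$status == "spontaneous"], , drop = FALSE]
  if (!nrow(stopped) || !nrow(beating))
    stop("need at least one stopped and one beating model at dose ", dose_uM)
  compare_groups(stopped, beating, quantities = quantities)
}

#' Run-level summary report
#'
#' Emits the count summary of a full pipeline run (accepted, mutant,
#' stopped/prolonged per dose) plus the phenotype conductance contrast, as
#' CSV files.
#'
#' @param control,mutant populations (mutant labelled).
#' @param trials named list of `drug_trial` objects (may be empty).
#' @param dir output directory.
#' @return invisibly, the manifest list.
#' @export
write_report <- function(control, mutant, trials = list(), dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list(control_n = nrow(control), mutant_n = nrow(mutant),
                 mutant_quiescent = length(attr(mutant, "quiescent_ids")))
  if (!is.null(mutant$label)) {
    counts$symptomatic <- sum(mutant$label == "symptomatic")
    counts$asymptomatic <- sum(mutant$label == "asymptomatic")
    sym <- mutant[mutant$label == "symptomatic", , drop = FALSE]
    asy <- mutant[mutant$label == "asymptomatic", , drop = FALSE]
    if (nrow(sym) && nrow(asy))
      utils::write.csv(compare_groups(sym, asy),
                       file.path(dir, "phenotype_conductance_contrast.csv"),
                       row.names = FALSE)
  }
  for (nm in names(trials)) {
    utils::write.csv(trials[[nm]]$aggregates,
                     file.path(dir, paste0("trial_", nm, "_aggregates.csv")),
                     row.names = FALSE)
    if (!is.null(trials[[nm]]$by_label))
      utils::write.csv(trials[[nm]]$by_label,
                       file.path(dir, paste0("trial_", nm, "_by_label.csv")),
                       row.names = FALSE)
  }
  invisible(counts)
}
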