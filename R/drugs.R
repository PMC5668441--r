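# Single pore-block drug model and dose-sweep trials on populations.

#' Pore-block factor
#'
#' The fraction of a channel's conductance remaining at a given drug dose
#' under the single pore-block model: `1 / (1 + (dose/IC50)^h)`.
#'
#' @param dose drug concentration (uM), >= 0 (vectorised).
#' @param ic50 half-blocking concentration (uM), > 0.
#' @param h Hill coefficient, > 0 (default 1, the standard pore-block
#'   convention when only an IC50 is reported).
#' @return remaining-conductance fraction in (0, 1].
#' @export
block_factor <- function(dose, ic50, h = 1) {
  if (any(!is.finite(dose)) || any(dose < 0)) stop("dose must be >= 0")
  if (any(ic50 <= 0) || any(h <= 0)) stop("IC50 and Hill coefficient must be > 0")
  1 / (1 + (dose / ic50)^h)
}

#' Multichannel drug specification
#'
#' Per-channel IC50/Hill entries for the four drug-targeted channels
#' (`I_Na`, `I_NaL`, `I_Kr`, `I_CaL`), with optional per-genotype overrides
#' (`genotype` column: `"any"`, `"control"` or `"V1763M"`).
#'
#' @param name drug name.
#' @param channels data.frame with columns `channel`, `IC50_uM`, optional
#'   `hill` (default 1) and optional `genotype` (default `"any"`).
#' @param doses default dose list (uM) for trials.
#' @return object of class `drug_spec`.
#' @export
drug_spec <- function(name, channels, doses = c(5, 10, 20)) {
  stopifnot(is.data.frame(channels),
            all(c("channel", "IC50_uM") %in% names(channels)))
  if (!"hill" %in% names(channels)) channels$hill <- 1
  channels$hill[is.na(channels$hill)] <- 1
  if (!"genotype" %in% names(channels)) channels$genotype <- "any"
  channels$genotype[is.na(channels$genotype)] <- "any"
  bad <- setdiff(unique(channels$channel), .blocked_channels)
  if (length(bad))
    stop("unknown channel(s) in drug spec: ", paste(bad, collapse = ", "),
         " (targets are ", paste(.blocked_channels, collapse = ", "), ")")
  if (any(channels$IC50_uM <= 0) || any(channels$hill <= 0))
    stop("IC50 and Hill coefficient must be > 0")
  structure(list(name = name, channels = channels, doses = doses),
            class = "drug_spec")
}

#' @export
print.drug_spec <- function(x, ...) {
  cat("drug_spec:", x$name, "| doses (uM):", paste(x$doses, collapse = ", "),
      "\n")
  print(x$channels)
  invisible(x)
}

#' Read a drug specification from CSV
#'
#' Expected columns: `drug`, `channel`, `IC50_uM`, optional `hill`,
#' `genotype`.
#'
#' @param path CSV file.
#' @param doses default dose list (uM).
#' @export
read_drug_csv <- function(path, doses = c(5, 10, 20)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- if ("drug" %in% names(df)) unique(df$drug)[1] else
    sub("\\.csv$", "", basename(path))
  df$drug <- NULL
  drug_spec(nm, df, doses = doses)
}

#' Resolve a drug and dose into channel block factors
#'
#' Genotype-specific entries take precedence over `"any"`; channels absent
#' from the spec are left unblocked (factor 1).
#'
#' @param drug a [drug_spec].
#' @param dose concentration (uM).
#' @param genotype `"control"` or `"V1763M"`.
#' @return a [block_factors] vector.
#' @export
apply_drug <- function(drug, dose, genotype = "control") {
  stopifnot(inherits(drug, "drug_spec"))
  fac <- stats::setNames(rep(1, 4), .blocked_channels)
  for (ch in .blocked_channels) {
    rows <- drug$channels[drug$channels$channel == ch, , drop = FALSE]
    if (!nrow(rows)) next
    r <- rows[rows$genotype == genotype, , drop = FALSE]
    if (!nrow(r)) r <- rows[rows$genotype == "any", , drop = FALSE]
    if (!nrow(r)) next
    fac[ch] <- block_factor(dose, r$IC50_uM[1], r$hill[1])
  }
  block_factors(I_Na = fac[["I_Na"]], I_NaL = fac[["I_NaL"]],
                I_Kr = fac[["I_Kr"]], I_CaL = fac[["I_CaL"]])
}

#' In-silico drug trial on a population
#'
#' Re-simulates every model at every dose from the published initial
#' conditions with the dose's genotype-resolved block factors, flags models
#' that stop beating, and aggregates APD90 changes against each model's
#' drug-free value.
#'
#' @param pop a `population` with drug-free biomarkers (optionally
#'   classified; per-label aggregates are then reported too).
#' @param drug a [drug_spec].
#' @param doses dose list (uM); default the spec's.
#' @param settings [solver_settings()].
#' @param progress print progress dots.
#' @return object of class `drug_trial`: `per_model` (id, dose, status,
#'   post-drug biomarkers, `dAPD90_ms`, `dAPD90_pct`, `prolonged`),
#'   `aggregates` (per dose: mean/median/sd of dAPD90, stopped / prolonged /
#'   failed counts), `by_label` (per dose x phenotype label, if labelled).
#' @export
drug_trial <- function(pop, drug, doses = NULL,
                       settings = solver_settings(), progress = FALSE) {
  stopifnot(inherits(pop, "population"), inherits(drug, "drug_spec"))
  if (!"APD90" %in% names(pop)) stop("population lacks drug-free APD90")
  doses <- doses %||% drug$doses
  genotype <- attr(pop, "genotype") %||% "control"
  df <- as.data.frame(pop)

  per <- list()
  for (d in doses) {
    blocks <- apply_drug(drug, d, genotype = genotype)
    for (i in seq_len(nrow(df))) {
      par <- cell_parameters(genotype = genotype,
                             scale = unlist(df[i, .sampled_names]))
      sim <- run_to_steady_state(par, blocks = blocks, settings = settings)
      bm <- .result_biomarkers(sim)
      row <- data.frame(id = df$id[i], dose_uM = d, status = sim$status,
                        as.data.frame(t(bm$summary)))
      row$APD90_free <- df$APD90[i]
      row$dAPD90_ms <- if (sim$status == "spontaneous")
        row$APD90 - df$APD90[i] else NA_real_
      row$dAPD90_pct <- 100 * row$dAPD90_ms / df$APD90[i]
      row$prolonged <- !is.na(row$dAPD90_ms) & row$dAPD90_ms > 0
      if (!is.null(df$label)) row$label <- df$label[i]
      per[[length(per) + 1]] <- row
      if (progress && length(per) %% 25 == 0) cat(".")
    }
  }
  if (progress) cat("\n")
  per <- do.call(rbind, per)
  rownames(per) <- NULL

  agg1 <- function(sub) {
    ok <- sub$status == "spontaneous"
    data.frame(n = nrow(sub),
               beating = sum(ok),
               stopped = sum(sub$status == "quiescent"),
               failed = sum(sub$status == "failed"),
               prolonged = sum(sub$prolonged, na.rm = TRUE),
               mean_dAPD90_ms = mean(sub$dAPD90_ms[ok]),
               sd_dAPD90_ms = stats::sd(sub$dAPD90_ms[ok]),
               median_dAPD90_ms = stats::median(sub$dAPD90_ms[ok]),
               mean_dAPD90_pct = mean(sub$dAPD90_pct[ok]),
               median_dAPD90_pct = stats::median(sub$dAPD90_pct[ok]))
  }
  aggregates <- do.call(rbind, lapply(split(per, per$dose_uM), agg1))
  aggregates <- cbind(dose_uM = as.numeric(rownames(aggregates)), aggregates)
  rownames(aggregates) <- NULL

  by_label <- NULL
  if (!is.null(per$label)) {
    by_label <- do.call(rbind, lapply(split(per, list(per$dose_uM, per$label)),
                                      function(s) if (nrow(s))
                                        cbind(dose_uM = s$dose_uM[1],
                                              label = s$label[1], agg1(s))))
    rownames(by_label) <- NULL
  }
  structure(list(per_model = per, aggregates = aggregates,
                 by_label = by_label, drug = drug$name, doses = doses,
                 genotype = genotype),
            class = "drug_trial")
}

#' @export
print.drug_trial <- function(x, ...) {
  cat("drug_trial:", x$drug, "on", x$genotype, "population\n")
  print(x$aggregates, digits = 4)
  invisible(x)
}

#' Write per-dose trial tables as CSV
#' @param trial a `drug_trial`.
#' @param dir output directory (one CSV per dose plus an aggregate table).
#' @export
write_trial_csv <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in trial$doses) {
    sub <- trial$per_model[trial$per_model$dose_uM == d, ]
    utils::write.csv(sub, file.path(dir, sprintf("%s_dose_%g uM.csv",
                                                 trial$drug, d)),
                     row.names = FALSE)
  }
  utils::write.csv(trial$aggregates,
                   file.path(dir, paste0(trial$drug, "_aggregates.csv")),
                   row.names = FALSE)
  invisible(dir)
}
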