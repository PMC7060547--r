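.pct <- function(x) 100 * x / sum(x)

#' Relative organism ratios from a mixture fit
#'
#' The deconvolved composition: each reference's fitted abundance `N_k` as
#' a percentage of the summed abundances. This is the shared-peptide-free
#' quantity the signature fit exists to provide.
#'
#' @param fit A `mixture_fit` from [fit_signatures()], or a numeric vector
#'   of fitted `N` values.
#' @return Named numeric vector of percentages summing to 100.
#' @export
relative_ratios <- function(fit) {
  N <- if (inherits(fit, "mixture_fit")) {
    stats::setNames(fit$par_table$N, fit$par_table$ref)
  } else {
    fit
  }
  if (sum(N) <= 0) stop("all fitted abundances are zero")
  .pct(N)
}

#' Naive total-TSM ratio (comparison estimator)
#'
#' Ratio of the references' raw TSM counts. Biased upward for organisms
#' with many shared peptides; provided to quantify that bias against the
#' signature-based estimate.
#'
#' @param table A `tsm_table`.
#' @param refs Reference taxon ids present in the table.
#' @param rank Rank at which to read the counts; default `"assigned"`.
#' @return Named percentages summing to 100.
#' @export
total_tsm_ratio <- function(table, refs, rank = "assigned") {
  refs <- as.character(refs)
  sub <- table[table$rank == rank, , drop = FALSE]
  tsm <- sub$tsm[match(refs, sub$taxid)]
  if (anyNA(tsm)) stop("reference(s) absent from table at rank ", rank)
  if (sum(tsm) == 0) stop("references carry no TSMs at rank ", rank)
  stats::setNames(.pct(tsm), refs)
}

#' Specific-peptide ratio (comparison estimator)
#'
#' Ratio of the references' taxon-specific peptide counts at a rank.
#' Sensitive to genome sequencing density: densely sequenced clades lose
#' specific peptides to their neighbors.
#'
#' @param table A `tsm_table`.
#' @param refs Reference taxon ids resolvable at `rank`.
#' @param rank Canonical rank; default `"species"`.
#' @return Named percentages summing to 100.
#' @export
specific_peptide_ratio <- function(table, refs, rank = "species") {
  refs <- as.character(refs)
  sub <- table[table$rank == rank, , drop = FALSE]
  sp <- sub$specific_peptides[match(refs, sub$taxid)]
  sp[is.na(sp)] <- 0
  if (sum(sp) == 0) {
    stop("no specific peptides for any reference at rank ", rank,
         "; try a higher rank")
  }
  stats::setNames(.pct(sp), refs)
}

#' Two-unique-peptide spectral-count estimator (comparison)
#'
#' Protein-centric estimator: per reference, sums the spectral counts of
#' proteins identified with at least two unique peptides, then normalizes
#' across references.
#'
#' @param proteins Data frame with columns `ref` (taxon id the protein is
#'   assigned to), `spectral_count` and `unique_peptides`.
#' @param refs Reference taxon ids.
#' @param min_unique Minimum unique peptides per protein; default 2.
#' @return Named percentages summing to 100.
#' @export
two_unique_peptide_estimator <- function(proteins, refs, min_unique = 2) {
  refs <- as.character(refs)
  ok <- proteins[proteins$unique_peptides >= min_unique, , drop = FALSE]
  if (!nrow(ok)) stop("no protein has >= ", min_unique, " unique peptides")
  sc <- vapply(refs, function(r) {
    sum(ok$spectral_count[as.character(ok$ref) == r])
  }, 0)
  if (sum(sc) == 0) stop("no qualifying protein for any reference")
  stats::setNames(.pct(sc), refs)
}

#' Mean absolute percentage-point error
#'
#' Mean over samples of the absolute difference between estimated and
#' expected compositions, in percentage points (not relative error):
#' estimating 62% where 91% was expected contributes 29 points.
#'
#' @param estimated,expected Numeric vectors of percentages, same length.
#' @return A single percentage-point error.
#' @export
mape <- function(estimated, expected) {
  if (length(estimated) != length(expected)) {
    stop("estimated and expected differ in length")
  }
  mean(abs(estimated - expected))
}

#' Linearity of estimated versus expected composition
#'
#' Ordinary least-squares regression of the estimated percentages on the
#' expected ones, plus the coefficient of determination with respect to
#' the identity line (`R2_identity = 1 - SS_res(identity)/SS_tot`).
#'
#' @param estimated,expected Numeric percentage vectors (>= 3 points).
#' @return List with `r_squared`, `slope`, `intercept`, `r_squared_identity`.
#' @export
linearity <- function(estimated, expected) {
  if (length(estimated) != length(expected)) {
    stop("estimated and expected differ in length")
  }
  if (length(estimated) < 3L) stop("need at least 3 points")
  if (stats::sd(expected) == 0) stop("expected values are constant")
  m <- stats::lm(estimated ~ expected)
  ss_tot <- sum((estimated - mean(estimated))^2)
  ss_id <- sum((estimated - expected)^2)
  list(r_squared = 1 - sum(stats::residuals(m)^2) / ss_tot,
       slope = unname(stats::coef(m)[2L]),
       intercept = unname(stats::coef(m)[1L]),
       r_squared_identity = 1 - ss_id / ss_tot)
}

#' Cell-count ratios from genomic DNA composition
#'
#' Assuming one genome copy per cell, the number of cells of species `i`
#' is proportional to its DNA fraction divided by its genome size;
#' ratios are normalized to 100%.
#'
#' @param dna_percent DNA composition percentages.
#' @param genome_size_mb Genome sizes in Mb (positive).
#' @return Percentages summing to 100.
#' @export
cell_count_ratios <- function(dna_percent, genome_size_mb) {
  if (any(genome_size_mb <= 0)) stop("genome sizes must be positive")
  .pct(dna_percent / genome_size_mb)
}

#' Cell-volume proxy for relative biomass
#'
#' Product of the cell-count ratio and the per-cell volume, taken as a
#' rough proxy for protein biomass. Reported unnormalized by default
#' (the raw products, on a percent-times-volume scale, need not sum to
#' 100); `normalize = TRUE` rescales them to percentages.
#'
#' @param cell_count_ratio Percentages from [cell_count_ratios()].
#' @param volume_um3 Mean cell volumes in cubic micrometers.
#' @param normalize Rescale to sum to 100; default `FALSE`.
#' @return Numeric vector.
#' @export
volume_proxy_biomass <- function(cell_count_ratio, volume_um3,
                                 normalize = FALSE) {
  if (any(volume_um3 < 0)) stop("volumes must be non-negative")
  v <- cell_count_ratio * volume_um3
  if (normalize) .pct(v) else v
}

#' Relative biomass shares from signature-quantitation TSMs
#'
#' Each organism's fitted signature TSM quantity as a percentage of the
#' community total — the phylopeptidomics relative biomass contribution.
#'
#' @param signature_tsms Non-negative fitted TSM quantities.
#' @return Percentages summing to 100.
#' @export
signature_biomass_shares <- function(signature_tsms) {
  if (any(signature_tsms < 0)) stop("signature TSMs must be non-negative")
  if (sum(signature_tsms) == 0) stop("signature TSMs sum to zero")
  .pct(signature_tsms)
}

#' Reference composition table for the ZymoBIOMICS community standard
#'
#' The ten-species mock-community metadata (genomic DNA composition,
#' median genome size, estimated cell volume) together with the fitted
#' signature-quantitation TSMs, shipped as package data for the worked
#' biomass-arithmetic example.
#'
#' @return Data frame with columns `species`, `dna_percent`, `genome_mb`,
#'   `volume_um3`, `signature_tsm`.
#' @export
zymo_community <- function() {
  path <- system.file("extdata", "zymo_community.tsv",
                      package = "phylopep", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
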