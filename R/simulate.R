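.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Random taxon panel with ultrametric phylogenetic distances
#'
#' Draws a random coalescent (ultrametric) tree over `n_taxa` leaves,
#' takes its cophenetic distances and rescales them linearly into
#' `[spread_min, spread_max]` (off-diagonal entries). References are
#' chosen greedily for maximal mutual separation, so mixtures of their
#' signatures are identifiable. Deterministic for a given seed.
#'
#' @param n_taxa Panel size.
#' @param n_refs Number of reference organisms (`<= n_taxa`).
#' @param seed Integer seed; all randomness flows through it.
#' @param spread Length-2 numeric `(min, max)` with
#'   `0 <= min < max <= 1`.
#' @return List with `panel` (taxon ids `t1..tn`), `D` (a
#'   [distance_matrix()]) and `refs`.
#' @export
random_distance_panel <- function(n_taxa, n_refs, seed,
                                  spread = c(0.005, 0.4)) {
  stopifnot(n_refs >= 1L, n_refs <= n_taxa, n_taxa >= 2L,
            length(spread) == 2L, spread[1L] >= 0,
            spread[1L] < spread[2L], spread[2L] <= 1)
  .with_seed(seed, {
    tree <- ape::rcoal(n_taxa, tip.label = paste0("t", seq_len(n_taxa)))
    d <- ape::cophenetic.phylo(tree)
    off <- d[upper.tri(d)]
    if (max(off) > min(off)) {
      d <- spread[1L] + (d - min(off)) * (spread[2L] - spread[1L]) /
        (max(off) - min(off))
    } else {
      d[] <- spread[2L]  # degenerate panel: all pairs equally distant
    }
    diag(d) <- 0
    d <- d[paste0("t", seq_len(n_taxa)), paste0("t", seq_len(n_taxa))]
    D <- distance_matrix(d)
    # greedy max-min separation, seeded at the globally farthest pair
    refs <- rownames(D)[which(d == max(d), arr.ind = TRUE)[1L, ]]
    refs <- refs[seq_len(min(n_refs, 2L))]
    while (length(refs) < n_refs) {
      rest <- setdiff(rownames(D), refs)
      score <- vapply(rest, function(t) min(d[t, refs]), 0)
      refs <- c(refs, rest[which.max(score)])
    }
    list(panel = rownames(D), D = D, refs = refs[seq_len(n_refs)])
  })
}

#' Ground truth for a synthetic community
#'
#' @param panel Taxon ids.
#' @param D A [distance_matrix()] over the panel.
#' @param refs References (subset of the panel).
#' @param abundances Non-negative `N_k`, one per reference.
#' @param A,a,b Signature coefficients (recycled across references).
#' @param noise `"none"` or `"poisson"`.
#' @param seed Integer seed used when drawing noisy profiles.
#' @return A `community_truth` object.
#' @export
community_truth <- function(panel, D, refs, abundances,
                            A = 0.45, a = 0.013, b = 0.082,
                            noise = c("none", "poisson"), seed = 1L) {
  noise <- match.arg(noise)
  refs <- as.character(refs)
  stopifnot(all(refs %in% panel), all(abundances >= 0),
            length(abundances) == length(refs))
  k <- length(refs)
  params <- Map(signature_params, refs, abundances,
                rep_len(A, k), rep_len(a, k), rep_len(b, k))
  structure(list(panel = as.character(panel), D = D, refs = refs,
                 abundances = abundances, params = unname(params),
                 noise = noise, seed = as.integer(seed)),
            class = "community_truth")
}

#' Simulate a TSM profile from a community truth
#'
#' Expected count at each panel taxon is the accumulated mixture of the
#' reference signatures; with Poisson noise each count is an integer draw
#' with that mean (spectral counts are event counts).
#'
#' @param truth A [community_truth()].
#' @return Data frame with columns `taxid` and `tsm`.
#' @export
simulate_tsm_profile <- function(truth) {
  stopifnot(inherits(truth, "community_truth"))
  mu <- mixture_value(truth$params, truth$D, truth$panel)
  tsm <- if (truth$noise == "poisson") {
    .with_seed(truth$seed, stats::rpois(length(mu), mu))
  } else {
    unname(mu)
  }
  data.frame(taxid = truth$panel, tsm = tsm, stringsAsFactors = FALSE)
}

#' Simulate a two-organism mixture dilution series
#'
#' Emulates a laboratory-assembled dilution series: for each ratio
#' `r1:r2` the two references receive abundances proportional to the
#' ratio, scaled so they sum to `total_tsms`. Returns one simulated
#' profile per sample plus the expected-percentage design table used by
#' the accuracy metrics.
#'
#' @param panel,D,refs As produced by [random_distance_panel()]
#'   (`refs` must have length 2).
#' @param ratios List (or unnamed list of length-2 numerics) of mixing
#'   ratios, e.g. `list(c(1,0), c(1,0.1), c(1,1))`.
#' @param total_tsms Total reference abundance per sample.
#' @param seed Integer seed; each sample draws from an independent
#'   sub-seed derived from it.
#' @param noise `"none"` or `"poisson"`.
#' @param A,a,b Signature coefficients.
#' @return List with `profiles` (list of data frames), `design`
#'   (data frame sample/ratio1/ratio2/expected_pct_ref1/N1/N2) and
#'   `truths`.
#' @export
simulate_mixture_series <- function(panel, D, refs, ratios,
                                    total_tsms = 3000, seed = 1L,
                                    noise = c("poisson", "none"),
                                    A = 0.45, a = 0.013, b = 0.082) {
  noise <- match.arg(noise)
  stopifnot(length(refs) == 2L)
  profiles <- list()
  truths <- list()
  design <- data.frame()
  for (s in seq_along(ratios)) {
    r <- as.numeric(ratios[[s]])
    stopifnot(length(r) == 2L, all(r >= 0), sum(r) > 0)
    N <- total_tsms * r / sum(r)
    truth <- community_truth(panel, D, refs, N, A = A, a = a, b = b,
                             noise = noise,
                             seed = as.integer(seed) * 1000L + s)
    profiles[[s]] <- simulate_tsm_profile(truth)
    truths[[s]] <- truth
    design <- rbind(design, data.frame(
      sample = s, ratio1 = r[1L], ratio2 = r[2L],
      expected_pct_ref1 = 100 * r[1L] / sum(r),
      N1 = N[1L], N2 = N[2L]))
  }
  list(profiles = profiles, design = design, truths = truths)
}

#' The nine mixing ratios of the reference dilution series
#'
#' `1:0, 1:0.1, 1:0.2, 1:0.5, 1:1, 0.5:1, 0.2:1, 0.1:1, 0:1`.
#'
#' @return List of length-2 numeric vectors.
#' @export
dilution_series_ratios <- function() {
  list(c(1, 0), c(1, 0.1), c(1, 0.2), c(1, 0.5), c(1, 1),
       c(0.5, 1), c(0.2, 1), c(0.1, 1), c(0, 1))
}

.AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
         "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Synthetic peptidome with distance-dependent peptide sharing
#'
#' Generates toy species peptidomes in which the probability that a
#' peptide of species `i` also occurs in species `j` decays with their
#' phylogenetic distance (bi-exponential by default, mirroring the
#' signature model), then emits PSM records sampling those peptides.
#' This enables end-to-end tests from the PSM level through TSM counting
#' to the signature fit.
#'
#' @param n_species Number of species (panel `t1..tn`).
#' @param peptides_per_species Peptides generated per species.
#' @param sharing Function of distance returning a sharing probability in
#'   `[0, 1]`; default `0.45 * exp(-x/0.013) + 0.55 * exp(-x/0.082)`.
#' @param seed Integer seed.
#' @param D Optional [distance_matrix()] over `t1..tn`; drawn with
#'   [random_distance_panel()] when absent.
#' @return List with `pep2tax` (peptide -> taxa), `psms` (PSM data
#'   frame), `acc2tax` (accession map) and `D`.
#' @export
synthetic_peptidome <- function(n_species, peptides_per_species,
                                sharing = NULL, seed = 1L, D = NULL) {
  if (is.null(sharing)) {
    sharing <- function(x) 0.45 * exp(-x / 0.013) + 0.55 * exp(-x / 0.082)
  }
  if (is.null(D)) {
    D <- random_distance_panel(n_species, 1L, seed = seed)$D
  }
  species <- rownames(D)[seq_len(n_species)]
  .with_seed(seed + 1L, {
    pep2tax <- list()
    rows <- list()
    acc_rows <- list()
    idx <- 0L
    for (i in seq_along(species)) {
      for (p in seq_len(peptides_per_species)) {
        idx <- idx + 1L
        pep <- paste(sample(.AA, 9L, replace = TRUE), collapse = "")
        # unique amino-acid suffix (index in base 20) keeps sequences valid
        suffix <- .AA[(idx %/% c(8000L, 400L, 20L, 1L)) %% 20L + 1L]
        pep <- paste0(pep, paste(suffix, collapse = ""), "K")
        carriers <- species[i]
        others <- species[-i]
        if (length(others)) {
          pr <- vapply(others, function(j) sharing(D[species[i], j]), 0)
          carriers <- c(carriers, others[stats::runif(length(others)) < pr])
        }
        pep2tax[[pep]] <- sort(carriers)
        accs <- paste0("ACC_", carriers, "_", idx)
        acc_rows[[idx]] <- data.frame(accession = accs, taxid = carriers,
                                      stringsAsFactors = FALSE)
        rows[[idx]] <- data.frame(
          spectrum_id = paste0("S", idx),
          peptide = pep,
          expectation = stats::runif(1L, 1e-4, 0.05),
          accessions = paste(accs, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
    list(pep2tax = pep2tax,
         psms = do.call(rbind, rows),
         acc2tax = do.call(rbind, acc_rows),
         D = D)
  })
}
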