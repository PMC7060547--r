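#' Phylopeptidomic signature parameters
#'
#' Parameter set of one reference organism's signature
#' `y(x) = N * (A * exp(-x/a) + (1 - A) * exp(-x/b))`, the expected
#' taxon-to-spectrum-match (TSM) count of a taxon at phylogenetic distance
#' `x` from the reference. `N` is the reference's abundance on the TSM
#' scale, `A` partitions the two exponential decay terms (the fast decay
#' `a` dominating at short range, the slow decay `b` the long tail).
#'
#' @param ref Taxon id of the reference organism.
#' @param N Non-negative abundance (TSM scale).
#' @param A Repartition coefficient in `[0, 1]`.
#' @param a,b Positive decay coefficients (distance units).
#' @return A `signature_params` object.
#' @export
signature_params <- function(ref, N, A = 0.45, a = 0.013, b = 0.082) {
  stopifnot(N >= 0, A >= 0, A <= 1, a > 0, b > 0)
  structure(list(ref = as.character(ref), N = N, A = A, a = a, b = b),
            class = "signature_params")
}

#' @export
print.signature_params <- function(x, ...) {
  cat(sprintf("signature_params ref=%s N=%.2f A=%.3f a=%.4f b=%.4f\n",
              x$ref, x$N, x$A, x$a, x$b))
  invisible(x)
}

#' Evaluate a phylopeptidomic signature
#'
#' Expected TSM count attributed to a taxon at distance `x` from the
#' reference: `N * (A * exp(-x/a) + (1 - A) * exp(-x/b))`. At `x = 0` this
#' is exactly `N`; the value decays monotonically to 0 with distance.
#'
#' @param p A [signature_params()] object.
#' @param x Non-negative distance(s).
#' @return Expected TSM count(s), in `[0, N]`.
#' @export
signature_value <- function(p, x) {
  stopifnot(inherits(p, "signature_params"))
  if (any(x < 0)) stop("distance x must be non-negative")
  p$N * (p$A * exp(-x / p$a) + (1 - p$A) * exp(-x / p$b))
}

#' Expected TSM count under a mixture of signatures
#'
#' The accumulated signal at a taxon is the sum over all references of
#' their signatures evaluated at the taxon's distance to each reference;
#' a reference's own position receives its full `N` plus the other
#' references' shared-peptide leakage.
#'
#' @param params List of [signature_params()].
#' @param D A [distance_matrix()] covering all references and `taxon`.
#' @param taxon Taxon id(s) at which to evaluate.
#' @return Expected TSM count(s).
#' @export
mixture_value <- function(params, D, taxon) {
  taxon <- as.character(taxon)
  if (!all(taxon %in% rownames(D))) {
    stop("taxon absent from distance matrix: ",
         paste(setdiff(taxon, rownames(D)), collapse = ", "))
  }
  out <- numeric(length(taxon))
  for (p in params) {
    if (!p$ref %in% rownames(D)) {
      stop("reference absent from distance matrix: ", p$ref)
    }
    out <- out + signature_value(p, D[taxon, p$ref])
  }
  stats::setNames(out, taxon)
}

#' Filter the taxon panel entering the fit
#'
#' Retains taxa with MS/MS attribution (TSM count > 0), fewer than 10
#' missing marker COGs (strict), and a "Complete genome" assembly level.
#' Taxa without metadata are excluded and tallied.
#'
#' @param table A `tsm_table` (or any data frame with `taxid` and `tsm`).
#' @param metadata Data frame with columns `taxid`, `missing_cogs`,
#'   `assembly_level`.
#' @param rank Rank at which to take the panel; default `"assigned"`
#'   (the most resolved, leaf-level attribution).
#' @param max_missing Strict upper bound on missing COGs; default 10.
#' @param assembly Required assembly level; default `"Complete genome"`.
#' @return Character vector of retained taxon ids, with attribute
#'   `no_metadata` (count of attributed taxa lacking metadata).
#' @export
filter_fit_taxa <- function(table, metadata, rank = "assigned",
                            max_missing = 10,
                            assembly = "Complete genome") {
  sub <- table[table$rank == rank & table$tsm > 0, , drop = FALSE]
  m <- match(sub$taxid, as.character(metadata$taxid))
  no_meta <- sum(is.na(m))
  sub <- sub[!is.na(m), , drop = FALSE]
  m <- m[!is.na(m)]
  keep <- metadata$missing_cogs[m] < max_missing &
    metadata$assembly_level[m] == assembly
  structure(sub$taxid[keep], no_metadata = no_meta)
}

#' Fit specification for the signature deconvolution
#'
#' Bundles the references, start values, box bounds, parameter
#' normalization factors and termination tolerance of the bounded
#' least-squares fit. Defaults follow the standard setup: start at
#' `A = 0.45`, `a = 0.013`, `b = 0.082`, `N =` the reference's observed
#' TSM count; bounds `A0 +/- 0.05`, `a0 +/- 0.001`, `b0 +/- 0.001`,
#' `N` in `[0, 5 * N0]`; parameters explored after normalization by
#' `1/A0`, `1/a0`, `1/b0` and `1/100` (for `N`); termination tolerance
#' 0.01 on the relative objective decrease.
#'
#' @param references Character vector of reference taxon ids.
#' @param A0,a0,b0 Shared default coefficients.
#' @param A_halfwidth,ab_halfwidth Bound half-widths for `A` and for
#'   `a`/`b`.
#' @param N_factor Upper bound on `N` as a multiple of the start value.
#' @param tol Termination tolerance (> 0).
#' @return A `fit_spec` object.
#' @export
fit_spec <- function(references, A0 = 0.45, a0 = 0.013, b0 = 0.082,
                     A_halfwidth = 0.05, ab_halfwidth = 0.001,
                     N_factor = 5, tol = 0.01) {
  stopifnot(length(references) >= 1L, tol > 0,
            A_halfwidth >= 0, ab_halfwidth >= 0, ab_halfwidth < min(a0, b0))
  structure(list(references = as.character(references),
                 A0 = A0, a0 = a0, b0 = b0,
                 A_halfwidth = A_halfwidth, ab_halfwidth = ab_halfwidth,
                 N_factor = N_factor, tol = tol),
            class = "fit_spec")
}

.mixture_resid <- function(theta, y, X, nref) {
  # theta: (N, A, a, b) per reference, concatenated; X: panel x ref distances
  yhat <- numeric(length(y))
  for (k in seq_len(nref)) {
    p <- theta[(4L * (k - 1L) + 1L):(4L * k)]
    yhat <- yhat + p[1L] * (p[2L] * exp(-X[, k] / p[3L]) +
                              (1 - p[2L]) * exp(-X[, k] / p[4L]))
  }
  y - yhat
}

.mixture_obj <- function(theta, y, X, nref) {
  r <- .mixture_resid(theta, y, X, nref)
  sum(r * r)
}

.mixture_grad <- function(theta, y, X, nref) {
  r <- .mixture_resid(theta, y, X, nref)
  g <- numeric(length(theta))
  for (k in seq_len(nref)) {
    i <- 4L * (k - 1L)
    N <- theta[i + 1L]; A <- theta[i + 2L]
    a <- theta[i + 3L]; b <- theta[i + 4L]
    x <- X[, k]
    e1 <- exp(-x / a); e2 <- exp(-x / b)
    s <- A * e1 + (1 - A) * e2
    g[i + 1L] <- -2 * sum(r * s)
    g[i + 2L] <- -2 * sum(r * N * (e1 - e2))
    g[i + 3L] <- -2 * sum(r * N * A * e1 * x / a^2)
    g[i + 4L] <- -2 * sum(r * N * (1 - A) * e2 * x / b^2)
  }
  g
}

#' Deconvolve a TSM profile into per-reference abundances
#'
#' Minimizes the sum of squared errors between the observed per-taxon TSM
#' counts and the accumulated mixture of the references' signatures, over
#' the box-constrained parameters `(N_k, A_k, a_k, b_k)` of every
#' reference. The optimizer is a bounded quasi-Newton method (L-BFGS-B via
#' [stats::optim()]); the search space is normalized by the fit spec's
#' correction factors (implemented through `parscale`), the start point is
#' the spec's defaults (no random initialization — the fit is
#' deterministic), and termination follows the spec's relative-decrease
#' tolerance.
#'
#' @param observed Data frame with columns `taxid` and `tsm`: the TSM
#'   profile over the fitted taxon panel.
#' @param D A [distance_matrix()] covering the panel and the references.
#' @param spec A [fit_spec()]. References must appear in `observed` (their
#'   observed counts seed `N`).
#' @param start Optional list of [signature_params()] (one per reference,
#'   in spec order) overriding the default start point, e.g. to restart
#'   from a previous fit.
#' @return A `mixture_fit`: list with `params` (list of
#'   [signature_params()]), `par_table` (data frame ref/N/A/a/b/ratio_pct),
#'   `objective`, `residuals` (named by taxon), `fitted`, `panel`,
#'   `convergence` and `iterations`.
#' @export
fit_signatures <- function(observed, D, spec, start = NULL) {
  stopifnot(inherits(spec, "fit_spec"))
  observed$taxid <- as.character(observed$taxid)
  refs <- spec$references
  if (!all(refs %in% rownames(D))) {
    stop("reference absent from distance matrix: ",
         paste(setdiff(refs, rownames(D)), collapse = ", "))
  }
  panel <- observed$taxid[observed$taxid %in% rownames(D)]
  if (length(panel) < nrow(observed)) {
    warning(nrow(observed) - length(panel),
            " observed taxa lack distances and are dropped from the fit")
  }
  obs <- observed[match(panel, observed$taxid), , drop = FALSE]
  y <- as.numeric(obs$tsm)
  if (all(y == 0)) stop("no MS/MS attribution: all observed counts are zero")
  nref <- length(refs)
  if (length(panel) < nref * 4L) {
    warning("panel smaller than the number of free parameters; ",
            "the fit may be under-determined")
  }
  # near-coincident references make the N split unidentifiable
  if (nref > 1L) {
    dd <- D[refs, refs, drop = FALSE]
    off <- dd[upper.tri(dd)]
    if (any(off < 1e-3)) {
      warning("reference distances below the distance resolution; ",
              "signatures are nearly collinear and the abundance split ",
              "is poorly identified")
    }
  }

  X <- D[panel, refs, drop = FALSE]
  N0 <- vapply(refs, function(r) {
    v <- obs$tsm[obs$taxid == r]
    if (!length(v)) stop("reference ", r, " has no observed TSM count")
    as.numeric(v[1L])
  }, 0)

  start0 <- lower <- upper <- parscale <- numeric(0)
  for (k in seq_len(nref)) {
    start0 <- c(start0, N0[k], spec$A0, spec$a0, spec$b0)
    lower <- c(lower, 0, max(0, spec$A0 - spec$A_halfwidth),
               spec$a0 - spec$ab_halfwidth, spec$b0 - spec$ab_halfwidth)
    upper <- c(upper, spec$N_factor * N0[k],
               min(1, spec$A0 + spec$A_halfwidth),
               spec$a0 + spec$ab_halfwidth, spec$b0 + spec$ab_halfwidth)
    parscale <- c(parscale, 100, spec$A0, spec$a0, spec$b0)
  }
  # keep a zero-count reference feasible: a point bound N in [0,0] is fine
  upper <- pmax(upper, lower)

  if (!is.null(start)) {
    stopifnot(length(start) == nref)
    start0 <- unlist(lapply(start, function(p) c(p$N, p$A, p$a, p$b)))
    start0 <- pmin(pmax(start0, lower), upper)
  }

  fit <- stats::optim(
    par = start0, fn = .mixture_obj, gr = .mixture_grad,
    y = y, X = X, nref = nref,
    method = "L-BFGS-B", lower = lower, upper = upper,
    control = list(parscale = parscale,
                   factr = spec$tol / .Machine$double.eps,
                   maxit = 1000L)
  )

  theta <- fit$par
  params <- lapply(seq_len(nref), function(k) {
    i <- 4L * (k - 1L)
    signature_params(refs[k], N = theta[i + 1L], A = theta[i + 2L],
                     a = theta[i + 3L], b = theta[i + 4L])
  })
  resid <- .mixture_resid(theta, y, X, nref)
  Ns <- vapply(params, `[[`, 0, "N")
  ratio <- if (sum(Ns) > 0) 100 * Ns / sum(Ns) else rep(NA_real_, nref)
  par_table <- data.frame(
    ref = refs,
    N = Ns,
    A = vapply(params, `[[`, 0, "A"),
    a = vapply(params, `[[`, 0, "a"),
    b = vapply(params, `[[`, 0, "b"),
    ratio_pct = ratio,
    stringsAsFactors = FALSE
  )
  structure(list(params = params, par_table = par_table,
                 objective = fit$value,
                 residuals = stats::setNames(resid, panel),
                 fitted = stats::setNames(y - resid, panel),
                 observed = stats::setNames(y, panel),
                 panel = panel,
                 convergence = fit$convergence,
                 iterations = fit$counts[["function"]]),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("mixture_fit over", length(x$panel), "taxa,",
      nrow(x$par_table), "reference(s); objective =",
      format(x$objective, digits = 6), "\n")
  print(x$par_table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a fit report as TSV
#'
#' @param fit A `mixture_fit`.
#' @param path Output path for the per-reference table; the residual table
#'   goes to `<path>.residuals.tsv`.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  utils::write.table(fit$par_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  res <- data.frame(taxid = fit$panel, observed = fit$observed,
                    fitted = fit$fitted, residual = fit$residuals)
  utils::write.table(res, paste0(path, ".residuals.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
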