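#' Construct a pairwise phylogenetic distance matrix object
#'
#' @param d Symmetric numeric matrix with zero diagonal; dimnames are the
#'   taxon ids.
#' @return A `distance_matrix` (a classed matrix).
#' @export
distance_matrix <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d))) stop("distance matrix must carry taxon ids")
  if (!all(is.finite(d))) stop("distances must be finite")
  if (any(d < 0)) stop("distances must be non-negative")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  colnames(d) <- rownames(d)
  class(d) <- c("distance_matrix", class(d))
  d
}

#' Patristic (cophenetic) distances from a newick tree
#'
#' Leaf-to-leaf distance is the sum of branch lengths on the connecting
#' path. Parsing and the cophenetic computation are delegated to ape.
#'
#' @param newick A newick string or a path to a newick file.
#' @param normalize If `TRUE`, divide by the maximum pairwise distance so
#'   that values lie in `[0, 1]`; default `FALSE` (raw branch-length
#'   units).
#' @return A `distance_matrix` over the leaf labels.
#' @export
cophenetic_distances <- function(newick, normalize = FALSE) {
  tree <- if (file.exists(newick)) ape::read.tree(newick)
          else ape::read.tree(text = newick)
  if (is.null(tree)) stop("could not parse newick input")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("newick tree is missing branch lengths")
  }
  if (length(tree$tip.label) == 1L) {
    d <- matrix(0, 1, 1, dimnames = list(tree$tip.label, tree$tip.label))
    return(distance_matrix(d))
  }
  d <- ape::cophenetic.phylo(tree)
  if (normalize && max(d) > 0) d <- d / max(d)
  distance_matrix(d)
}

#' Validate a homology-search hit
#'
#' A hit qualifies when its e-value is strictly below 0.001, its percent
#' identity strictly above 45 and its coverage fraction strictly above
#' 0.94 — the acceptance rule for recruiting marker-gene (COG) homologs.
#'
#' @param evalue E-value of the hit (>= 0).
#' @param identity Percent identity in `[0, 100]`.
#' @param coverage Coverage fraction in `[0, 1]`.
#' @param max_evalue,min_identity,min_coverage The three strict thresholds.
#' @return Logical (vectorized over the inputs).
#' @export
validate_hit <- function(evalue, identity, coverage,
                         max_evalue = 0.001, min_identity = 45,
                         min_coverage = 0.94) {
  evalue < max_evalue & identity > min_identity & coverage > min_coverage
}

#' Read tabular homology hits (BLAST outfmt-6 dialect)
#'
#' Standard 12 columns (`qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore`); a 13th `qcovs`-style coverage
#' column is used when present, otherwise coverage must be supplied via
#' `query_lengths` (coverage = alignment length / query length).
#'
#' @param path Path to the tab-separated hits file (no header).
#' @param query_lengths Optional named vector of query sequence lengths.
#' @return Data frame with columns `cog`, `subject`, `identity`, `evalue`,
#'   `coverage` and the raw columns.
#' @export
read_homology_hits <- function(path, query_lengths = NULL) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  base <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (ncol(df) < 12L) stop("expected at least 12 tab-separated columns")
  names(df)[1:12] <- base
  if (ncol(df) >= 13L) {
    cov <- as.numeric(df[[13L]])
    if (any(cov > 1, na.rm = TRUE)) cov <- cov / 100  # qcovs is in percent
    df$coverage <- cov
  } else {
    if (is.null(query_lengths)) {
      stop("no coverage column; supply query_lengths to derive it")
    }
    df$coverage <- df$length / as.numeric(query_lengths[df$qseqid])
  }
  df$cog <- df$qseqid
  df$subject <- df$sseqid
  df$identity <- df$pident
  df
}

#' Select the best validated homolog per marker gene
#'
#' For each COG in the panel, keeps the best hit passing [validate_hit()]
#' (lowest e-value, ties broken by highest identity). COGs with no valid
#' hit fall back to the reference sequence and are flagged as missing.
#'
#' @param cog_ids Character vector of marker ids (e.g. the 31-COG panel).
#' @param hits Data frame of hits for one taxon, with columns `cog`,
#'   `subject`, `evalue`, `identity`, `coverage`, and `sequence` (the
#'   subject sequence to use).
#' @param fallback Named character vector of reference sequences, one per
#'   COG, used for missing markers.
#' @return List with elements `sequences` (named character, one per COG)
#'   and `missing` (character vector of flagged COG ids).
#' @export
select_cog_sequences <- function(cog_ids, hits, fallback) {
  seqs <- character(0)
  missing <- character(0)
  for (cog in cog_ids) {
    h <- hits[hits$cog == cog, , drop = FALSE]
    if (nrow(h)) {
      ok <- validate_hit(h$evalue, h$identity, h$coverage)
      h <- h[ok, , drop = FALSE]
    }
    if (!nrow(h)) {
      if (!cog %in% names(fallback)) {
        stop("no fallback reference sequence for missing COG ", cog)
      }
      seqs[cog] <- fallback[[cog]]
      missing <- c(missing, cog)
    } else {
      h <- h[order(h$evalue, -h$identity), , drop = FALSE]
      seqs[cog] <- h$sequence[1L]
    }
  }
  list(sequences = seqs, missing = missing)
}

#' Exclude taxa with too many missing marker genes
#'
#' Taxa missing strictly more than `limit` COGs are dropped from the
#' distance panel (a taxon at exactly the limit is retained).
#'
#' @param taxa Character vector of taxon ids.
#' @param missing_counts Integer vector, parallel to `taxa`.
#' @param limit Maximum tolerated number of missing COGs; default 10.
#' @return The retained taxon ids.
#' @export
exclude_high_missing <- function(taxa, missing_counts, limit = 10) {
  stopifnot(length(taxa) == length(missing_counts))
  keep <- missing_counts <= limit
  if (!any(keep)) warning("all taxa excluded (missing-COG limit)")
  taxa[keep]
}

.as_char_matrix <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("alignment is ragged")
  do.call(rbind, strsplit(seqs, "", fixed = TRUE))
}

#' Conservation mask over alignment columns (gblocks-like)
#'
#' A column is *conserved* when its modal non-gap residue is held by
#' strictly more than `min_fraction` of the block's sequences (gaps never
#' disqualify a column by themselves, but gap rows do count in the
#' denominator). Conserved columns separated by runs of at most
#' `max_nonconserved_run` non-conserved columns form blocks; a run longer
#' than that splits the region, and surviving blocks with fewer than
#' `min_block` conserved columns are discarded. The mask keeps the
#' conserved columns of surviving blocks (non-conserved positions are
#' always masked out).
#'
#' @param alignment Character vector of equal-length aligned sequences
#'   (one superkingdom block), `-` for gaps.
#' @param min_fraction Strict conservation threshold; default 0.5.
#' @param max_nonconserved_run Longest tolerated internal run of
#'   non-conserved columns; default 8.
#' @param min_block Minimum block span; default 2.
#' @return Logical vector over columns (`TRUE` = kept).
#' @export
conservation_mask <- function(alignment, min_fraction = 0.5,
                              max_nonconserved_run = 8, min_block = 2) {
  m <- .as_char_matrix(alignment)
  n <- nrow(m)
  conserved <- apply(m, 2L, function(col) {
    res <- col[col != "-"]
    if (!length(res)) return(FALSE)
    max(table(res)) > min_fraction * n
  })
  ncol_aln <- length(conserved)
  mask <- rep(FALSE, ncol_aln)
  idx <- which(conserved)
  if (!length(idx)) return(mask)
  # group conserved columns into blocks: a gap > max_nonconserved_run
  # between consecutive conserved columns starts a new block
  breaks <- c(0L, which(diff(idx) - 1L > max_nonconserved_run), length(idx))
  for (b in seq_len(length(breaks) - 1L)) {
    block <- idx[(breaks[b] + 1L):breaks[b + 1L]]
    if (length(block) >= min_block) mask[block] <- TRUE
  }
  mask
}

#' Union of per-superkingdom masks
#'
#' A column survives the combined mask when any input mask keeps it.
#'
#' @param masks List of equal-length logical vectors.
#' @return Logical vector.
#' @export
union_masks <- function(masks) {
  stopifnot(length(masks) >= 1L)
  lens <- lengths(masks)
  if (length(unique(lens)) != 1L) stop("masks differ in length")
  Reduce(`|`, masks)
}

#' Apply a column mask to aligned sequences
#'
#' @param seqs Character vector of aligned sequences.
#' @param mask Logical vector over columns.
#' @return Masked sequences.
#' @export
apply_mask <- function(seqs, mask) {
  m <- .as_char_matrix(seqs)
  if (ncol(m) != length(mask)) stop("mask length does not match alignment")
  out <- apply(m[, mask, drop = FALSE], 1L, paste, collapse = "")
  stats::setNames(out, names(seqs))
}

#' Percent identity between two aligned sequences
#'
#' Computed over columns where neither sequence carries a gap: 100 times
#' the number of identical residue pairs divided by the number of
#' comparable columns; 0 when no column is comparable.
#'
#' @param a,b Equal-length aligned sequences (`-` for gaps).
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  comparable <- ca != "-" & cb != "-"
  if (!any(comparable)) return(0)
  100 * sum(ca[comparable] == cb[comparable]) / sum(comparable)
}

#' Distance matrix from a percent-identity matrix over supervectors
#'
#' All-pairs percent identity on the aligned, masked supervectors, turned
#' into a `[0, 1]` dissimilarity as `d = 1 - PI/100` (the fractional
#' complement of identity).
#'
#' @param supervectors Named character vector of aligned supervector
#'   sequences (names are taxon ids), all the same length.
#' @return A `distance_matrix`.
#' @export
pim_to_distances <- function(supervectors) {
  n <- length(supervectors)
  if (is.null(names(supervectors))) stop("supervectors must be named by taxon")
  if (length(unique(nchar(supervectors))) != 1L) {
    stop("supervectors differ in length")
  }
  d <- matrix(0, n, n, dimnames = list(names(supervectors),
                                       names(supervectors)))
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        pid <- percent_identity(supervectors[[i]], supervectors[[j]])
        d[i, j] <- d[j, i] <- 1 - pid / 100
      }
    }
  }
  distance_matrix(d)
}

#' Deduplicate taxa with identical marker-gene sets
#'
#' Taxa whose per-COG sequences are byte-identical form a group; one
#' representative (the smallest taxon id) is aligned and scored, the rest
#' inherit its distances.
#'
#' @param cog_sets Named list, taxon id -> named character vector of COG
#'   sequences.
#' @return List with `representatives` (taxon ids) and `inherits` (named
#'   character vector mapping every taxon to its representative).
#' @export
dedup_identical_cog_sets <- function(cog_sets) {
  fp <- vapply(cog_sets, function(s) {
    paste(names(s)[order(names(s))], s[order(names(s))],
          sep = "=", collapse = "\r")
  }, "")
  taxa <- names(cog_sets)
  smallest <- function(ids) {
    if (!anyNA(suppressWarnings(as.numeric(ids)))) {
      ids[order(as.numeric(ids))][1L]
    } else sort(ids)[1L]
  }
  reps <- vapply(split(taxa, fp), smallest, "")
  inherits_map <- stats::setNames(unname(reps[fp]), taxa)
  list(representatives = sort(unique(unname(reps))),
       inherits = inherits_map)
}

#' Read / write distance tables
#'
#' Long format is `taxid_a <TAB> taxid_b <TAB> distance` with a header;
#' wide format is a plain matrix with row and column names.
#'
#' @param path File path.
#' @return For the reader, a `distance_matrix`.
#' @export
read_distances <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("taxid_a", first)) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = c("character", "character",
                                           "numeric"))
    taxa <- sort(unique(c(df$taxid_a, df$taxid_b)))
    d <- matrix(0, length(taxa), length(taxa),
                dimnames = list(taxa, taxa))
    d[cbind(df$taxid_a, df$taxid_b)] <- df$distance
    d[cbind(df$taxid_b, df$taxid_a)] <- df$distance
  } else {
    d <- as.matrix(utils::read.delim(path, row.names = 1L,
                                     check.names = FALSE))
  }
  distance_matrix(d)
}

#' @rdname read_distances
#' @param d A `distance_matrix`.
#' @param format `"long"` or `"wide"`.
#' @export
write_distances <- function(d, path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (format == "wide") {
    utils::write.table(cbind(taxid = rownames(d), as.data.frame(unclass(d))),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    taxa <- rownames(d)
    idx <- which(upper.tri(d), arr.ind = TRUE)
    df <- data.frame(taxid_a = taxa[idx[, 1L]], taxid_b = taxa[idx[, 2L]],
                     distance = d[idx])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
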