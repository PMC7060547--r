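#' Read a PSM table from TSV
#'
#' Expected columns: `spectrum_id`, `peptide`, `expectation`, `accessions`
#' (semicolon-separated protein accessions). Extra columns pass through.
#'
#' @param path Path to a tab-separated PSM file with a header line.
#' @return A data frame of PSM records.
#' @export
read_psms <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("spectrum_id", "peptide", "expectation", "accessions")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("PSM table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$expectation <- as.numeric(df$expectation)
  df
}

#' Read an accession-to-taxon mapping table
#'
#' Two tab-separated columns (`accession`, `taxid`); an accession may map
#' to several taxa (multimap), one row each.
#'
#' @param path Path to the TSV file (header optional, auto-detected).
#' @return A data frame with columns `accession` and `taxid` (character).
#' @export
read_acc2tax <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("accession", first, ignore.case = TRUE)
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE, colClasses = "character")
  names(df)[1:2] <- c("accession", "taxid")
  df[, c("accession", "taxid")]
}

.split_accessions <- function(x) strsplit(x, ";", fixed = TRUE)

#' Validate PSMs by expectation value
#'
#' Keeps records whose search-engine expectation value is strictly below
#' `threshold`. Several surviving records may share one spectrum id
#' (multiple PSMs per MS/MS spectrum are allowed).
#'
#' @param records PSM data frame (see [read_psms()]).
#' @param threshold Positive expectation cutoff; default 0.1.
#' @return The filtered data frame.
#' @export
validate_psms <- function(records, threshold = 0.1) {
  stopifnot(is.numeric(threshold), threshold > 0)
  records[records$expectation < threshold, , drop = FALSE]
}

#' Remove contaminant accessions from PSM records
#'
#' Contaminant accessions (keratins, trypsin, ... as in cRAP) are stripped
#' from each record's accession list; records left with no accession are
#' dropped entirely so contaminant-only spectra never reach taxa mapping.
#'
#' @param records PSM data frame.
#' @param contaminant_accessions Character vector of accessions to remove.
#' @return The cleaned data frame.
#' @export
exclude_contaminants <- function(records, contaminant_accessions) {
  if (!length(contaminant_accessions) || !nrow(records)) return(records)
  accs <- .split_accessions(records$accessions)
  cleaned <- lapply(accs, function(a) setdiff(a, contaminant_accessions))
  keep <- lengths(cleaned) > 0L
  records <- records[keep, , drop = FALSE]
  records$accessions <- vapply(cleaned[keep], paste, "", collapse = ";")
  records
}

#' Read a contaminant accession list
#'
#' One accession per line; cRAP-style FASTA header lines (`>acc desc`) are
#' accepted and reduced to the accession token.
#'
#' @param path Path to the list file.
#' @return Character vector of accessions.
#' @export
read_contaminants <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  fasta <- startsWith(lines, ">")
  lines[fasta] <- sub("^>\\s*", "", lines[fasta])
  vapply(strsplit(lines, "\\s+"), `[[`, "", 1L)
}

#' Map peptides to taxa through protein accessions
#'
#' Each peptide's taxon set is the union, over every record containing it,
#' of the taxa its accessions map to. Unmapped accessions are skipped and
#' tallied (mapping tables are always incomplete in metaproteomics); if
#' nothing maps at all, an empty map is returned with a warning.
#'
#' @param records PSM data frame.
#' @param acc2tax Accession-to-taxid data frame (see [read_acc2tax()]).
#' @return A named list, peptide sequence -> character vector of taxon ids,
#'   with attribute `unmapped_accessions` (count of accession lookups that
#'   found no taxon).
#' @export
map_peptides_to_taxa <- function(records, acc2tax) {
  if (!nrow(records)) {
    return(structure(list(), unmapped_accessions = 0L))
  }
  accs <- .split_accessions(records$accessions)
  long <- data.frame(
    peptide   = rep(records$peptide, lengths(accs)),
    accession = unlist(accs),
    stringsAsFactors = FALSE
  )
  long <- unique(long)
  merged <- merge(long, acc2tax, by = "accession")
  n_unmapped <- sum(!long$accession %in% acc2tax$accession)
  if (!nrow(merged)) {
    warning("no accession of any record could be mapped to a taxon")
    return(structure(list(), unmapped_accessions = n_unmapped))
  }
  pep2tax <- lapply(split(merged$taxid, merged$peptide),
                    function(t) sort(unique(t)))
  structure(pep2tax, unmapped_accessions = n_unmapped)
}

#' Count taxon-to-spectrum matches and roll up to canonical ranks
#'
#' The central counting step. A taxon-to-spectrum match (TSM) is an MS/MS
#' spectrum assigned to a taxon via any of its matched peptides; a spectrum
#' contributes at most once to a taxon's TSM count even when several of its
#' peptides map there. Counts are produced at the direct assignment level
#' (rank `"assigned"`) and, via lineage rollup with per-rank deduplication
#' of spectra and peptides, at the seven canonical ranks.
#'
#' At rank r, a peptide is *specific* to taxon t when its full taxon set
#' resolves to t and only t at that rank; a peptide whose set contains an
#' organism that does not resolve at r is not specific to anything there.
#' A spectrum is a *specific TSM* of t at r when every one of its mapped
#' peptides is specific to t.
#'
#' @param records Validated PSM data frame.
#' @param pep2tax Peptide-to-taxa map from [map_peptides_to_taxa()].
#' @param tree A [load_taxonomy()] tree.
#' @return A `tsm_table`: data frame with columns `rank`, `taxid`, `name`,
#'   `tsm`, `psm`, `peptides`, `specific_peptides`, `specific_tsms`.
#'   Taxa absent from the tree are pooled in a synthetic `"unplaced"` bin
#'   at the canonical ranks and reported via attribute `unplaced_taxa`.
#' @export
count_tsms <- function(records, pep2tax, tree) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  pairs <- unique(records[, c("spectrum_id", "peptide"), drop = FALSE])
  pairs <- pairs[pairs$peptide %in% names(pep2tax), , drop = FALSE]

  all_taxa <- unique(unlist(pep2tax, use.names = FALSE))
  known <- all_taxa[all_taxa %in% names(tree$parent) |
                      all_taxa %in% names(tree$merged)]
  unplaced <- setdiff(all_taxa, known)

  # per-rank taxon -> group id ("" = does not resolve at this rank)
  roll_map <- function(rank) {
    if (rank == "assigned") {
      stats::setNames(all_taxa, all_taxa)
    } else {
      g <- vapply(all_taxa, function(t) {
        if (t %in% unplaced) return("unplaced")
        a <- lineage_at_level(tree, t, rank)
        if (is.na(a)) "" else a
      }, "")
      stats::setNames(g, all_taxa)
    }
  }

  ranks <- c("assigned", CANONICAL_RANKS)
  out <- vector("list", length(ranks))
  names(out) <- ranks

  for (rank in ranks) {
    rmap <- roll_map(rank)
    # peptide -> set of rank-level groups; "" marks an unresolved member
    pep_groups <- lapply(pep2tax, function(taxa) unique(unname(rmap[taxa])))
    groups <- sort(setdiff(unique(unlist(pep_groups)), ""))
    if (!length(groups)) next
    specific_of <- vapply(pep_groups, function(g) {
      if (length(g) == 1L && g != "") g else NA_character_
    }, "")
    by_spec <- split(pairs$peptide, pairs$spectrum_id)

    rows <- lapply(groups, function(g) {
      peps_g <- names(pep_groups)[vapply(pep_groups, function(x) g %in% x,
                                         NA)]
      sub <- pairs[pairs$peptide %in% peps_g, , drop = FALSE]
      spec_peps <- names(specific_of)[!is.na(specific_of) &
                                        specific_of == g]
      # spectra all of whose mapped peptides are specific to g
      spec_tsm <- sum(vapply(by_spec,
                             function(p) all(p %in% spec_peps), NA))
      data.frame(
        rank = rank, taxid = g,
        name = if (g %in% names(tree$name)) tree$name[[g]] else g,
        tsm = length(unique(sub$spectrum_id)),
        psm = nrow(sub),
        peptides = length(unique(sub$peptide)),
        specific_peptides = sum(spec_peps %in% sub$peptide),
        specific_tsms = spec_tsm,
        stringsAsFactors = FALSE
      )
    })
    out[[rank]] <- do.call(rbind, rows)
  }

  res <- do.call(rbind, out[!vapply(out, is.null, NA)])
  rownames(res) <- NULL
  class(res) <- c("tsm_table", "data.frame")
  attr(res, "unplaced_taxa") <- unplaced
  res
}

#' TSM profile at a rank
#'
#' All taxa carrying at least one TSM at the given rank, ordered by
#' decreasing TSM count (ties by ascending taxon id) — the ordering used
#' for ranked-abundance displays.
#'
#' @param table A `tsm_table` from [count_tsms()].
#' @param rank Rank label present in the table.
#' @return Data frame with columns `taxid` and `tsm`.
#' @export
tsm_profile <- function(table, rank) {
  sub <- table[table$rank == rank & table$tsm > 0, , drop = FALSE]
  sub <- sub[order(-sub$tsm, sub$taxid), c("taxid", "tsm"), drop = FALSE]
  rownames(sub) <- NULL
  as.data.frame(sub)
}

#' Write a TSM table as long-format TSV
#'
#' @param table A `tsm_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsm_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
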