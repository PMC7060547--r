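#' Canonical taxonomic ranks
#'
#' The seven canonical ranks used for count rollup, ordered from the most
#' resolved (species) to the least (superkingdom).
#'
#' @export
CANONICAL_RANKS <- c("species", "genus", "family", "order", "class",
                     "phylum", "superkingdom")

.split_dmp_line <- function(lines) {
  # NCBI dumps delimit fields with "\t|\t" and terminate lines with "\t|";
  # some derived files use a bare "|". Accept both, trimming whitespace.
  lines <- sub("\\s*\\|\\s*$", "", lines)
  parts <- strsplit(lines, "\\s*\\|\\s*")
  lapply(parts, function(p) trimws(p))
}

#' Load an NCBI-style taxonomy from nodes/names dump text
#'
#' Parses the pipe-delimited `nodes.dmp` / `names.dmp` dialect into a
#' navigable tree. Both the tab-pipe-tab and bare-pipe delimiters are
#' accepted. When a taxon has several names, the "scientific name" class is
#' preferred; ids without any name receive a `taxid:<id>` placeholder.
#'
#' @param nodes_file Path to a `nodes.dmp`-format file
#'   (`tax_id | parent tax_id | rank | ...`).
#' @param names_file Path to a `names.dmp`-format file
#'   (`tax_id | name | unique name | name class`), or `NULL` for
#'   placeholder names throughout.
#' @param merged_file Optional `merged.dmp`-format file
#'   (`old_id | new_id`); old ids are remembered and remapped on lookup.
#'
#' @return An object of class `taxonomy_tree`: a list with elements
#'   `parent`, `rank`, `name` (named by taxon id), `root` (the root id) and
#'   `merged` (named remapping vector, possibly empty).
#'
#' @details Duplicate `tax_id` lines with identical content are silently
#'   merged; duplicates with differing content keep the last occurrence and
#'   emit a warning. A node whose parent is absent from the file, or a
#'   parent chain that cycles without reaching the root, is a structural
#'   error naming the offending id.
#'
#' @examples
#' nodes <- textConnection(c("1\t|\t1\t|\tno rank\t|",
#'                           "2\t|\t1\t|\tsuperkingdom\t|",
#'                           "562\t|\t2\t|\tspecies\t|"))
#' tree <- load_taxonomy(nodes)
#' lineage_at_level(tree, "562", "superkingdom")
#' @export
load_taxonomy <- function(nodes_file, names_file = NULL, merged_file = NULL) {
  read_lines <- function(x) {
    if (inherits(x, "connection")) readLines(x) else readLines(x, warn = FALSE)
  }
  lines <- read_lines(nodes_file)
  lines <- lines[nzchar(trimws(lines))]
  fields <- .split_dmp_line(lines)
  bad <- vapply(fields, length, 0L) < 3L
  if (any(bad)) {
    stop("malformed nodes line(s): ", paste(which(bad)[1], collapse = ", "))
  }
  taxid  <- vapply(fields, `[[`, "", 1L)
  parent <- vapply(fields, `[[`, "", 2L)
  rank   <- vapply(fields, `[[`, "", 3L)

  # Deduplicate: identical duplicate lines merge silently, conflicting
  # duplicates keep the last occurrence with a warning.
  key <- paste(taxid, parent, rank, sep = "\r")
  keep <- !duplicated(key, fromLast = TRUE)
  taxid <- taxid[keep]; parent <- parent[keep]; rank <- rank[keep]
  if (anyDuplicated(taxid)) {
    dup_ids <- unique(taxid[duplicated(taxid)])
    warning("conflicting duplicate node lines for tax_id(s) ",
            paste(dup_ids, collapse = ", "), "; last occurrence kept")
    keep <- !duplicated(taxid, fromLast = TRUE)
    taxid <- taxid[keep]; parent <- parent[keep]; rank <- rank[keep]
  }

  parent_map <- stats::setNames(parent, taxid)
  rank_map   <- stats::setNames(rank, taxid)

  root <- taxid[taxid == parent]
  if (length(root) != 1L) {
    stop("expected exactly one root node (parent == self), found ",
         length(root))
  }

  missing_parent <- setdiff(parent, taxid)
  if (length(missing_parent)) {
    offender <- taxid[match(missing_parent[1], parent)]
    stop("node ", offender, " references missing parent ", missing_parent[1])
  }

  # Cycle check: every node must reach the root in < n steps.
  n <- length(taxid)
  for (id in taxid) {
    cur <- id
    steps <- 0L
    while (cur != root) {
      cur <- parent_map[[cur]]
      steps <- steps + 1L
      if (steps > n) stop("cycle detected in taxonomy at tax_id ", id)
    }
  }

  name_map <- stats::setNames(paste0("taxid:", taxid), taxid)
  if (!is.null(names_file)) {
    nlines <- read_lines(names_file)
    nlines <- nlines[nzchar(trimws(nlines))]
    nf <- .split_dmp_line(nlines)
    nid    <- vapply(nf, `[[`, "", 1L)
    nname  <- vapply(nf, `[[`, "", 2L)
    nclass <- vapply(nf, function(p) if (length(p) >= 4L) p[[4L]] else "", "")
    known <- nid %in% taxid
    # any name first, then scientific names overwrite
    ord <- order(nclass[known] == "scientific name")
    name_map[nid[known][ord]] <- nname[known][ord]
  }

  merged <- character(0)
  if (!is.null(merged_file)) {
    mlines <- read_lines(merged_file)
    mlines <- mlines[nzchar(trimws(mlines))]
    mf <- .split_dmp_line(mlines)
    merged <- stats::setNames(vapply(mf, `[[`, "", 2L),
                              vapply(mf, `[[`, "", 1L))
  }

  structure(list(parent = parent_map, rank = rank_map, name = name_map,
                 root = root, merged = merged),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("taxonomy_tree with", length(x$parent), "nodes; root =", x$root, "\n")
  tab <- table(x$rank)
  cat("ranks:", paste(names(tab), tab, sep = ":", collapse = ", "), "\n")
  invisible(x)
}

.resolve_taxid <- function(tree, taxid) {
  taxid <- as.character(taxid)
  if (length(tree$merged) && taxid %in% names(tree$merged)) {
    taxid <- tree$merged[[taxid]]
  }
  if (!taxid %in% names(tree$parent)) {
    stop("unknown taxon id: ", taxid)
  }
  taxid
}

.lineage <- function(tree, taxid) {
  # taxid and all ancestors up to the root, in order
  out <- character(0)
  cur <- taxid
  repeat {
    out <- c(out, cur)
    if (cur == tree$root) break
    cur <- tree$parent[[cur]]
  }
  out
}

#' Ancestor of a taxon at a canonical rank
#'
#' Walks the lineage of `taxid` towards the root and returns the unique
#' ancestor (or the taxon itself) carrying the requested rank label, or
#' `NA` when the lineage has no node at that rank.
#'
#' @param tree A [load_taxonomy()] tree.
#' @param taxid Taxon id (coerced to character).
#' @param level One of the seven canonical ranks (see [CANONICAL_RANKS]).
#' @return The taxon id at `level`, or `NA_character_`.
#' @export
lineage_at_level <- function(tree, taxid, level) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  if (!level %in% CANONICAL_RANKS) {
    stop("level must be one of: ", paste(CANONICAL_RANKS, collapse = ", "))
  }
  taxid <- .resolve_taxid(tree, taxid)
  lin <- .lineage(tree, taxid)
  hit <- lin[tree$rank[lin] == level]
  if (length(hit)) hit[[1L]] else NA_character_
}

#' Node-count distance between two taxa
#'
#' The number of edges traversed on the unique path `a` to `b` through
#' their lowest common ancestor in the taxonomic tree.
#'
#' @param tree A [load_taxonomy()] tree.
#' @param a,b Taxon ids.
#' @return A non-negative integer.
#' @export
node_path_distance <- function(tree, a, b) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  a <- .resolve_taxid(tree, a)
  b <- .resolve_taxid(tree, b)
  if (a == b) return(0L)
  la <- .lineage(tree, a)
  lb <- .lineage(tree, b)
  lca <- la[la %in% lb][1L]
  (match(lca, la) - 1L) + (match(lca, lb) - 1L)
}

#' Closest member of a pre-aligned taxon set
#'
#' Among a set of taxa whose marker sequences are already in the reference
#' alignment, returns the one closest to `taxid` in node-count distance.
#' Ties break deterministically to the smallest taxon id (numeric when all
#' ids are numeric, lexicographic otherwise).
#'
#' @param tree A [load_taxonomy()] tree.
#' @param taxid Taxon id to place.
#' @param prealigned Non-empty vector of taxon ids already aligned.
#' @return A single taxon id from `prealigned`.
#' @export
closest_prealigned_taxon <- function(tree, taxid, prealigned) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  prealigned <- as.character(prealigned)
  if (!length(prealigned)) stop("prealigned set must be non-empty")
  d <- vapply(prealigned, function(p) node_path_distance(tree, taxid, p), 0L)
  cand <- prealigned[d == min(d)]
  if (!anyNA(suppressWarnings(as.numeric(cand)))) {
    cand[order(as.numeric(cand))][1L]
  } else {
    sort(cand)[1L]
  }
}
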