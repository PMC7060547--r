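# Fixture builders and independent oracles shared across the test files.

# Write dmp-format text to a temp file and return its path.
dmp_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".dmp",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# A small hand-built taxonomy:
#
#   1 root
#   +-- 2 superkingdom Bacteria
#       +-- 10 phylum
#           +-- 20 class
#               +-- 30 order
#                   +-- 40 family
#                       +-- 50 genus
#                       |   +-- 60 species A   -> 61 strain A1, 62 strain A2
#                       |   +-- 70 species B   -> 71 strain B1
#                       +-- 51 genus2
#                           +-- 80 species C
toy_nodes <- c(
  "1\t|\t1\t|\tno rank\t|",
  "2\t|\t1\t|\tsuperkingdom\t|",
  "10\t|\t2\t|\tphylum\t|",
  "20\t|\t10\t|\tclass\t|",
  "30\t|\t20\t|\torder\t|",
  "40\t|\t30\t|\tfamily\t|",
  "50\t|\t40\t|\tgenus\t|",
  "51\t|\t40\t|\tgenus\t|",
  "60\t|\t50\t|\tspecies\t|",
  "70\t|\t50\t|\tspecies\t|",
  "80\t|\t51\t|\tspecies\t|",
  "61\t|\t60\t|\tno rank\t|",
  "62\t|\t60\t|\tno rank\t|",
  "71\t|\t70\t|\tno rank\t|"
)

toy_names <- c(
  "1\t|\troot\t|\t\t|\tscientific name\t|",
  "2\t|\tBacteria\t|\t\t|\tscientific name\t|",
  "60\t|\tSpecies A\t|\t\t|\tscientific name\t|",
  "60\t|\tspA\t|\t\t|\tsynonym\t|",
  "70\t|\tSpecies B\t|\t\t|\tscientific name\t|"
)

toy_tree <- function() {
  load_taxonomy(dmp_file(toy_nodes), dmp_file(toy_names))
}

# PSM data frame builder
psm_df <- function(spectrum, peptide, expectation = 0.01,
                   accessions = peptide) {
  data.frame(spectrum_id = spectrum, peptide = peptide,
             expectation = expectation, accessions = accessions,
             stringsAsFactors = FALSE)
}

# Independent brute-force oracle for count_tsms: explicit loops over
# spectra x peptides x taxa, no shared code with the implementation.
oracle_count_tsms <- function(records, pep2tax, tree, rank) {
  pairs <- unique(records[, c("spectrum_id", "peptide")])
  pairs <- pairs[pairs$peptide %in% names(pep2tax), , drop = FALSE]
  known <- names(tree$parent)
  roll <- function(taxon) {
    if (rank == "assigned") return(taxon)
    if (!taxon %in% known) return("unplaced")
    a <- lineage_at_level(tree, taxon, rank)
    if (is.na(a)) "" else a
  }
  taxa_all <- unique(unlist(pep2tax))
  groups <- unique(vapply(taxa_all, roll, ""))
  groups <- sort(setdiff(groups, ""))
  out <- list()
  for (g in groups) {
    tsm_specs <- character(0); psm_n <- 0L; peps <- character(0)
    spec_peps <- character(0)
    for (pep in names(pep2tax)) {
      gs <- unique(vapply(pep2tax[[pep]], roll, ""))
      if (g %in% gs) {
        rows <- pairs[pairs$peptide == pep, , drop = FALSE]
        tsm_specs <- union(tsm_specs, rows$spectrum_id)
        psm_n <- psm_n + nrow(rows)
        if (nrow(rows)) peps <- union(peps, pep)
      }
      if (length(gs) == 1L && gs == g) spec_peps <- c(spec_peps, pep)
    }
    spec_peps <- intersect(spec_peps, pairs$peptide)
    st <- 0L
    for (s in unique(pairs$spectrum_id)) {
      ps <- pairs$peptide[pairs$spectrum_id == s]
      if (length(ps) && all(ps %in% spec_peps)) st <- st + 1L
    }
    out[[g]] <- data.frame(rank = rank, taxid = g,
                           tsm = length(tsm_specs), psm = psm_n,
                           peptides = length(peps),
                           specific_peptides = length(spec_peps),
                           specific_tsms = st,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Random toy PSM dataset over the toy taxonomy's leaf taxa
random_tsm_input <- function(seed, n_spectra = 30, n_peptides = 12,
                             taxa = c("61", "62", "71", "80")) {
  set.seed(seed)
  peptides <- paste0("PEP", LETTERS[seq_len(n_peptides)])
  pep2tax <- lapply(seq_len(n_peptides), function(i) {
    sort(sample(taxa, sample(seq_along(taxa), 1)))
  })
  names(pep2tax) <- peptides
  rows <- lapply(seq_len(n_spectra), function(s) {
    k <- sample(1:3, 1)
    data.frame(spectrum_id = paste0("S", s),
               peptide = sample(peptides, k),
               expectation = 0.01,
               accessions = "ACC",
               stringsAsFactors = FALSE)
  })
  list(records = do.call(rbind, rows), pep2tax = pep2tax)
}

# All-pairs shortest-path oracle for node_path_distance on a taxonomy:
# breadth-first search over the undirected parent-child graph.
oracle_path_distance <- function(tree, a, b) {
  ids <- names(tree$parent)
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    p <- tree$parent[[id]]
    if (p != id) {
      adj[[id]] <- union(adj[[id]], p)
      adj[[p]] <- union(adj[[p]], id)
    }
  }
  dist <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  dist[a] <- 0L
  queue <- a
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    for (nb in adj[[cur]]) {
      if (is.na(dist[nb])) {
        dist[nb] <- dist[cur] + 1L
        queue <- c(queue, nb)
      }
    }
  }
  unname(dist[b])
}
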