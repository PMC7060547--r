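test_that("cophenetic_distances sums branch lengths on leaf paths", {
  D <- cophenetic_distances("((A:1,B:1):1,C:2);")
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(D["B", "C"], 4)
  expect_equal(diag(D), c(A = 0, B = 0, C = 0))
  # additivity on the 3-leaf tree: d(A,C) = d(A,root) + d(root,C) etc.
  expect_equal(D["A", "C"] + D["B", "C"] - D["A", "B"], 2 * 3)

  expect_identical(dim(cophenetic_distances("(A:1);")), c(1L, 1L))

  star <- cophenetic_distances("(A:0.3,B:0.3,C:0.3,D:0.3);")
  off <- star[upper.tri(star)]
  expect_true(all(abs(off - 0.6) < 1e-12))

  norm <- cophenetic_distances("((A:1,B:1):1,C:2);", normalize = TRUE)
  expect_equal(max(norm), 1)
  expect_equal(norm["A", "B"], 0.5)
})

test_that("cophenetic_distances rejects trees without branch lengths or with duplicate leaves", {
  expect_error(cophenetic_distances("((A,B),C);"), "branch length")
  expect_error(cophenetic_distances("((A:1,A:1):1,C:2);"), "duplicate")
})

test_that("validate_hit applies the three strict thresholds", {
  expect_true(validate_hit(1e-5, 60, 0.95))
  expect_false(validate_hit(1e-5, 45.0, 0.95))   # identity must exceed 45
  expect_false(validate_hit(0.001, 60, 0.95))    # e-value strictly below
  expect_false(validate_hit(1e-5, 60, 0.94))     # coverage strictly above
  expect_identical(validate_hit(c(1e-5, 0.01), c(60, 60), c(0.95, 0.95)),
                   c(TRUE, FALSE))
})

test_that("select_cog_sequences picks lowest e-value, ties by identity, falls back on missing", {
  hits <- data.frame(
    cog = c("COG0012", "COG0012", "COG0016", "COG0016"),
    subject = c("s1", "s2", "s3", "s4"),
    evalue = c(1e-8, 1e-10, 1e-6, 1e-6),
    identity = c(70, 60, 50, 60),
    coverage = c(0.99, 0.99, 0.95, 0.95),
    sequence = c("AAAA", "BBBB", "CCCC", "DDDD"),
    stringsAsFactors = FALSE
  )
  fallback <- c(COG0012 = "RRRR", COG0016 = "SSSS", COG0048 = "TTTT")
  sel <- select_cog_sequences(c("COG0012", "COG0016", "COG0048"),
                              hits, fallback)
  expect_identical(unname(sel$sequences["COG0012"]), "BBBB")  # lowest e-value
  expect_identical(unname(sel$sequences["COG0016"]), "DDDD")  # identity tie-break
  expect_identical(unname(sel$sequences["COG0048"]), "TTTT")  # fallback
  expect_identical(sel$missing, "COG0048")

  # invalid hits do not rescue a COG
  bad <- hits; bad$coverage <- 0.5
  sel2 <- select_cog_sequences(c("COG0012"), bad, fallback)
  expect_identical(sel2$missing, "COG0012")
})

test_that("exclude_high_missing keeps taxa at the limit, drops strictly above", {
  taxa <- c("a", "b", "c")
  expect_identical(exclude_high_missing(taxa, c(10, 11, 0)), c("a", "c"))
  expect_warning(out <- exclude_high_missing(taxa, c(11, 12, 13)),
                 "all taxa excluded")
  expect_length(out, 0L)
})

test_that("conservation_mask follows the strict majority rule", {
  # 4 sequences; column 1: A,A,A,C conserved (3/4 > 0.5);
  # column 2: A,A,C,C not conserved (2/4 == 0.5, strict)
  aln <- c("AA", "AA", "AC", "CC")
  mask <- conservation_mask(aln, min_block = 1)
  expect_identical(mask, c(TRUE, FALSE))
  # gaps do not disqualify: A,A,-,- has modal residue A held by 2/4 (not >0.5)
  # but A,A,A,- has 3/4 -> conserved
  expect_identical(conservation_mask(c("A", "A", "A", "-"), min_block = 1),
                   TRUE)
  expect_error(conservation_mask(c("AA", "A")), "ragged")
})

test_that("long non-conserved runs split blocks and short blocks are dropped", {
  # conserved col, 9 non-conserved cols, conserved col -> run of 9 > 8
  # splits; both blocks span 1 < 2 and are discarded
  cons <- c("A", "A", "A")
  vary <- c("A", "C", "G")
  cols <- c(list(cons), rep(list(vary), 9), list(cons))
  aln <- apply(do.call(cbind, cols), 1, paste, collapse = "")
  expect_false(any(conservation_mask(aln)))
  # with a run of 8 the two conserved columns bridge into one block that
  # meets the minimum of 2 conserved columns; only they survive the mask
  cols8 <- c(list(cons), rep(list(vary), 8), list(cons))
  aln8 <- apply(do.call(cbind, cols8), 1, paste, collapse = "")
  mask8 <- conservation_mask(aln8)
  expect_identical(which(mask8), c(1L, 10L))
})

test_that("conservation_mask limiting behavior", {
  set.seed(1)
  aa <- c("A", "C", "D", "E")
  aln <- replicate(4, paste(sample(aa, 30, replace = TRUE), collapse = ""))
  # min_fraction near 1 keeps only perfectly conserved gap-free columns
  m_strict <- conservation_mask(aln, min_fraction = 0.999, min_block = 1,
                                max_nonconserved_run = 1e9)
  expect_true(all(which(m_strict) %in% which(
    apply(do.call(rbind, strsplit(aln, "")), 2,
          function(x) length(unique(x)) == 1))))
  cols <- do.call(rbind, strsplit(aln, ""))
  perfect <- apply(cols, 2, function(x) length(unique(x)) == 1 &&
                     all(x != "-"))
  expect_identical(m_strict, unname(perfect))
  # min_fraction 0 with unlimited runs keeps every non-gap column
  m_all <- conservation_mask(aln, min_fraction = 0, min_block = 1,
                             max_nonconserved_run = 1e9)
  expect_true(all(m_all))
})

test_that("union_masks is columnwise OR", {
  expect_identical(union_masks(list(c(TRUE, TRUE, FALSE, FALSE),
                                    c(FALSE, TRUE, TRUE, FALSE))),
                   c(TRUE, TRUE, TRUE, FALSE))
  m <- c(TRUE, FALSE)
  expect_identical(union_masks(list(m)), m)
  expect_identical(union_masks(list(c(FALSE, FALSE), c(FALSE, FALSE))),
                   c(FALSE, FALSE))
  expect_error(union_masks(list(TRUE, c(TRUE, FALSE))), "length")
})

test_that("percent_identity counts identical pairs over gap-free columns", {
  expect_equal(percent_identity("ACDEFG", "ACDEYG"), 100 * 5 / 6)
  expect_equal(percent_identity("ACDEFG", "ACDEFG"), 100)
  # columns with a gap in either sequence are excluded: only cols 1 and 3
  # are comparable and both match
  expect_equal(percent_identity("A-CD", "AEC-"), 100)
  expect_equal(percent_identity("--", "AA"), 0)  # nothing comparable
  expect_error(percent_identity("AA", "A"), "length")
})

test_that("percent_identity is symmetric and column-permutation invariant", {
  set.seed(7)
  aa <- c("A", "C", "D", "-")
  for (i in 1:20) {
    a <- paste(sample(aa, 40, replace = TRUE), collapse = "")
    b <- paste(sample(aa, 40, replace = TRUE), collapse = "")
    expect_equal(percent_identity(a, b), percent_identity(b, a))
    perm <- sample(40)
    ap <- paste(strsplit(a, "")[[1]][perm], collapse = "")
    bp <- paste(strsplit(b, "")[[1]][perm], collapse = "")
    expect_equal(percent_identity(ap, bp), percent_identity(a, b))
  }
})

test_that("pim_to_distances yields a symmetric [0,1] matrix with zero diagonal", {
  sv <- c(x = "ACDEFG", y = "ACDEYG", z = "ACDEFG")
  D <- pim_to_distances(sv)
  expect_s3_class(D, "distance_matrix")
  expect_equal(D["x", "z"], 0)               # identical supervectors
  expect_equal(D["x", "y"], 1 - 5 / 6)       # 83.333% identity pair
  expect_equal(unclass(D), t(unclass(D)), ignore_attr = TRUE)
  expect_true(all(D >= 0 & D <= 1))
  expect_error(pim_to_distances(c(x = "AA", y = "A")), "length")
})

test_that("apply_mask keeps flagged columns only", {
  out <- apply_mask(c(a = "ABCD", b = "EFGH"),
                    c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(out, c(a = "AC", b = "EG"))
})

test_that("dedup_identical_cog_sets groups byte-identical marker sets", {
  sets <- list(
    "102" = c(COG1 = "AAA", COG2 = "BBB"),
    "101" = c(COG2 = "BBB", COG1 = "AAA"),  # same content, other order
    "103" = c(COG1 = "AAA", COG2 = "XXX")
  )
  out <- dedup_identical_cog_sets(sets)
  expect_identical(out$representatives, c("101", "103"))
  expect_identical(unname(out$inherits[c("101", "102", "103")]),
                   c("101", "101", "103"))
  # all distinct -> identity mapping
  out2 <- dedup_identical_cog_sets(list("1" = c(C = "A"), "2" = c(C = "B")))
  expect_identical(unname(out2$inherits), c("1", "2"))
  # inherited taxon's distances equal its representative's by construction
  sv <- c("101" = "AAABBB", "103" = "AAAXXX")
  D <- pim_to_distances(sv)
  d102_103 <- D[out$inherits[["102"]], "103"]
  expect_equal(d102_103, D["101", "103"])
})

test_that("distance tables round-trip through long and wide TSV", {
  D <- pim_to_distances(c(a = "ACDEFG", b = "ACDEYG", c = "AWWWFG"))
  for (fmt in c("long", "wide")) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_distances(D, path, format = fmt)
    D2 <- read_distances(path)
    expect_equal(unclass(D2)[rownames(D), colnames(D)], unclass(D),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("distance_matrix validates its invariants", {
  m <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"),
                                                   c("a", "b")))
  expect_s3_class(distance_matrix(m), "distance_matrix")
  bad <- m; bad[1, 2] <- -0.1; bad[2, 1] <- -0.1
  expect_error(distance_matrix(bad), "non-negative")
  asym <- m; asym[1, 2] <- 0.5
  expect_error(distance_matrix(asym), "symmetric")
  nodiag <- m; diag(nodiag) <- 0.2
  expect_error(distance_matrix(nodiag), "diagonal")
})

test_that("read_homology_hits derives coverage and feeds validate_hit", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("COG0012", "subj1", "60.0", "95", "5", "0",
                     "1", "95", "1", "95", "1e-20", "200"),
                   collapse = "\t"), path)
  hits <- read_homology_hits(path, query_lengths = c(COG0012 = 100))
  expect_equal(hits$coverage, 0.95)
  expect_true(validate_hit(hits$evalue, hits$identity, hits$coverage))
})
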