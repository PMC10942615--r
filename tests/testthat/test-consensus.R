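mini_deltas <- function(start, end, significant, direction, delta,
                        timepoint = 3000) {
  data.frame(start = start, end = end, timepoint_s = timepoint,
             delta = delta, significant = significant,
             direction = direction, stringsAsFactors = FALSE)
}

test_that("consensus mapping reproduces the per-position enumeration on a worked case", {
  p <- protein_sequence("demo", paste(rep("A", 10), collapse = ""))
  map <- build_peptide_map(p, rbind(c(1, 5), c(4, 9)))
  d <- mini_deltas(c(1, 4), c(5, 9), c(TRUE, FALSE),
                   c("protected", "none"), c(-0.5, -0.1))
  sm <- map_significance_to_residues(d, map, 3000, rule = "any")
  expect_equal(sm$status, c("uncovered", rep("protected", 4),
                            rep("insignificant", 4), "uncovered"))
  expect_equal(sm$n_peptides, c(0, 1, 1, 1, 2, 1, 1, 1, 1, 0))
  expect_equal(sm$mean_delta_da[5], mean(c(-0.5, -0.1)))
  expect_true(is.na(sm$mean_delta_da[1]))
})

test_that("rules any/majority/all behave as documented", {
  p <- protein_sequence("demo", paste(rep("A", 10), collapse = ""))
  map <- build_peptide_map(p, rbind(c(1, 6), c(2, 6)))
  d <- mini_deltas(c(1, 2), c(6, 6), c(TRUE, FALSE),
                   c("protected", "none"), c(-0.5, -0.1))
  # residues 3..6 have two contributors, one significant
  sm_any <- map_significance_to_residues(d, map, 3000, "any")
  expect_equal(sm_any$status[3:6], rep("protected", 4))
  sm_all <- map_significance_to_residues(d, map, 3000, "all")
  expect_equal(sm_all$status[3:6], rep("insignificant", 4))
  sm_maj <- map_significance_to_residues(d, map, 3000, "majority")
  expect_equal(sm_maj$status[3:6], rep("insignificant", 4))
  # residue 2 is covered only by the significant peptide
  expect_equal(sm_all$status[2], "protected")

  # no significant peptide -> no protected/deprotected position
  d0 <- d; d0$significant <- FALSE; d0$direction <- "none"
  sm0 <- map_significance_to_residues(d0, map, 3000, "any")
  expect_false(any(sm0$status %in% c("protected", "deprotected")))

  expect_error(map_significance_to_residues(d, map, 42), "timepoint")
})

test_that("direction conflicts resolve toward protection", {
  p <- protein_sequence("demo", paste(rep("A", 8), collapse = ""))
  map <- build_peptide_map(p, rbind(c(1, 6), c(2, 7)))
  d <- mini_deltas(c(1, 2), c(6, 7), c(TRUE, TRUE),
                   c("protected", "deprotected"), c(-0.5, 0.5))
  expect_message(sm <- map_significance_to_residues(d, map, 3000, "any"),
                 "conflict")
  expect_equal(sm$status[3:6], rep("protected", 4))
  expect_equal(sm$status[7], "deprotected")
})

test_that("consensus mapping agrees with brute force on random instances", {
  set.seed(41)
  for (i in 1:60) {
    L <- sample(15:40, 1)
    seq <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], L,
                        replace = TRUE), collapse = "")
    p <- protein_sequence("rand", seq)
    n <- sample(2:8, 1)
    starts <- sample(1:(L - 4), n, replace = TRUE)
    ends <- pmin(starts + sample(3:9, n, replace = TRUE), L)
    keep <- !duplicated(paste(starts, ends))
    starts <- starts[keep]; ends <- ends[keep]
    map <- build_peptide_map(p, cbind(starts, ends))
    sig <- runif(length(starts)) < 0.4
    dirs <- ifelse(!sig, "none",
                   ifelse(runif(length(starts)) < 0.7, "protected",
                          "deprotected"))
    d <- mini_deltas(starts, ends, sig, dirs,
                     ifelse(dirs == "deprotected", 0.5, -0.5))
    rule <- sample(c("any", "majority", "all"), 1)
    sm <- suppressMessages(map_significance_to_residues(d, map, 3000, rule))
    expect_equal(sm$status, brute_consensus(p, d, rule))
    # conservation: counts sum to protein length
    expect_equal(sum(position_counts(sm)), L)
  }
})

test_that("adding a significant peptide only promotes residues under rule any", {
  p <- protein_sequence("demo", paste(rep("A", 20), collapse = ""))
  map1 <- build_peptide_map(p, rbind(c(1, 8), c(10, 16)))
  d1 <- mini_deltas(c(1, 10), c(8, 16), c(FALSE, FALSE), c("none", "none"),
                    c(0, 0))
  map2 <- build_peptide_map(p, rbind(c(1, 8), c(10, 16), c(5, 12)))
  d2 <- rbind(d1, mini_deltas(5, 12, TRUE, "protected", -0.6))
  s1 <- map_significance_to_residues(d1, map1, 3000, "any")$status
  s2 <- map_significance_to_residues(d2, map2, 3000, "any")$status
  rank <- c(uncovered = 0, insignificant = 1, protected = 2, deprotected = 2)
  expect_true(all(rank[s2] >= rank[s1]))
})

test_that("status counts on an all-uncovered map equal the protein length", {
  p <- protein_sequence("demo", paste(rep("A", 12), collapse = ""))
  # a single no-amide peptide leaves everything uncovered
  map1 <- build_peptide_map(p, cbind(1, 1))
  d1 <- mini_deltas(1, 1, FALSE, "none", 0)
  counts <- position_counts(map_significance_to_residues(d1, map1, 3000))
  expect_equal(unname(counts["uncovered"]), 12L)
})

test_that("structure annotation writes B-factors and round-trips", {
  p <- protein_sequence("demo", paste(rep("A", 10), collapse = ""),
                        numbering_offset = -1L)
  map <- build_peptide_map(p, rbind(c(1, 5), c(4, 9)))
  d <- mini_deltas(c(1, 4), c(5, 9), c(TRUE, FALSE),
                   c("protected", "none"), c(-0.5, -0.1))
  sm <- map_significance_to_residues(d, map, 3000)

  pdb_in <- tempfile(fileext = ".pdb")
  make_ca_pdb(pdb_in, resnos = c(0:9, 50))   # 50 is unmatched
  pdb_out <- tempfile(fileext = ".pdb")
  suppressWarnings(write_structure_annotation(sm, pdb_in, pdb_out))
  re <- suppressWarnings(bio3d::read.pdb(pdb_out))
  b <- re$atom$b
  # display positions 1..4 (construct 2..5) are protected with mean delta -0.5
  expect_equal(b[re$atom$resno == 1], -0.5)
  expect_equal(b[re$atom$resno == 4], -0.3)   # construct 5: mean(-0.5, -0.1)
  expect_equal(b[re$atom$resno == 5], 0)      # insignificant
  expect_equal(b[re$atom$resno == 50], -99)   # unmatched sentinel

  # idempotence: re-annotating the annotated file yields the same values
  pdb_out2 <- tempfile(fileext = ".pdb")
  suppressWarnings(write_structure_annotation(sm, pdb_out, pdb_out2))
  re2 <- suppressWarnings(bio3d::read.pdb(pdb_out2))
  expect_equal(re2$atom$b, b)

  # status codes
  pdb_out3 <- tempfile(fileext = ".pdb")
  suppressWarnings(write_structure_annotation(sm, pdb_in, pdb_out3,
                                              value = "status_code"))
  re3 <- suppressWarnings(bio3d::read.pdb(pdb_out3))
  expect_equal(re3$atom$b[re3$atom$resno == 1], -1)
  expect_equal(re3$atom$b[re3$atom$resno == 9], -2)  # uncovered construct 10

  # all-insignificant map -> all matched B-factors 0
  d0 <- mini_deltas(c(1, 4), c(5, 9), c(FALSE, FALSE), c("none", "none"),
                    c(0, 0))
  sm0 <- map_significance_to_residues(d0, map, 3000)
  pdb_out4 <- tempfile(fileext = ".pdb")
  suppressWarnings(write_structure_annotation(sm0, pdb_in, pdb_out4))
  re4 <- suppressWarnings(bio3d::read.pdb(pdb_out4))
  expect_true(all(re4$atom$b[re4$atom$resno != 50] == 0))
})
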