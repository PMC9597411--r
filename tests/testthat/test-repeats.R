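test_that("blast6 ingestion applies the E-value cutoff as a closed bound", {
  lines <- c(
    "SAIR_LF_p1_p2|g1\ttoyRE01\t95.0\t100\t5\t0\t11\t110\t1\t100\t1e-20\t180",
    "SAIR_LF_p1_p2|g1\ttoyRE02\t90.0\t80\t8\t0\t200\t121\t1\t80\t1e-05\t90",
    "SAIR_IF_p3_p4|g1\ttoyRE03\t88.0\t60\t7\t0\t5\t64\t60\t1\t1e-04\t70")
  f <- withr::local_tempfile(lines = lines)
  hits <- load_hits(f, dialect = "blast6", e_cutoff = 1e-5)
  expect_equal(nrow(hits), 2)  # the 1e-04 hit is dropped, 1e-05 kept
  expect_true(all(hits$evalue <= 1e-5))
  # reversed (minus-strand) coordinates are normalised, 1-based -> 0-based
  rev <- hits[hits$element_id == "toyRE02", ]
  expect_equal(rev$start, 120)
  expect_equal(rev$end, 200)
  expect_equal(hits$genome, c("g1", "g1"))
  expect_equal(hits$sair_id, c("SAIR_LF_p1_p2", "SAIR_LF_p1_p2"))
})

test_that("nhmmer tblout ingestion reads ali coordinates and E-values", {
  hdr <- "# target name        accession  query name           accession  hmmfrom hmm to alifrom ali to envfrom env to  sq len strand   E-value  score  bias  description of target"
  mk <- function(target, q, alifrom, alito, ev, sc) {
    paste(target, "-", q, "-", 1, 100, alifrom, alito, 1, 100, 5000,
          if (alifrom <= alito) "+" else "-", ev, sc, "0.1", "-")
  }
  f <- withr::local_tempfile(lines = c(
    hdr,
    mk("SAIR_MF_p5_p6|g2", "DfamX", 901, 1000, "2.1e-08", 55.2),
    mk("SAIR_MF_p5_p6|g2", "DfamY", 450, 391, "1e-05", 20.0),
    mk("SAIR_MF_p5_p6|g2", "DfamZ", 10, 60, "0.002", 9.0)))
  hits <- load_hits(f, dialect = "nhmmer", e_cutoff = 1e-5)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$element_id, c("DfamX", "DfamY"))
  expect_equal(hits$start, c(900, 390))
  expect_equal(hits$end, c(1000, 450))
  expect_equal(hits$genome, c("g2", "g2"))
})

test_that("region merging requires a shared base and is idempotent", {
  hits <- tibble::tibble(
    element_id = c("e1", "e2", "e3", "e4"),
    sair_id = "s1", genome = "g1",
    start = c(10, 49, 50, 20), end = c(50, 90, 90, 30))
  # [10,50) and [49,90) overlap by one base -> merged; [50,90) overlaps the
  # merged run; nested [20,30) absorbed
  reg <- merge_regions(hits)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, 10)
  expect_equal(reg$end, 90)
  # abutting intervals (zero overlap) stay separate
  ab <- tibble::tibble(element_id = c("a", "b"), sair_id = "s1",
                       start = c(10, 50), end = c(50, 90))
  expect_equal(nrow(merge_regions(ab)), 2)
  # idempotence and order-invariance
  reg2 <- merge_regions(dplyr::mutate(reg, element_id = "m"))
  expect_equal(reg2$start, reg$start)
  expect_equal(reg2$end, reg$end)
  shuf <- hits[c(3, 1, 4, 2), ]
  reg3 <- merge_regions(shuf)
  expect_equal(reg3$start, reg$start)
  expect_equal(reg3$end, reg$end)
})

test_that("local alignment matches the quadratic DP oracle", {
  a80 <- strrep("ACGT", 20)
  la <- local_align(a80, a80)
  expect_equal(la$score, 320)  # 80 x 4
  expect_equal(la$length, 80)
  a50 <- random_dna_str(50)
  la50 <- local_align(a50, a50)
  expect_equal(la50$score, 200)
  expect_equal(la50$length, 50)
  # deletion case: 100-mer vs itself with a 3-base deletion
  set.seed(77)
  q <- random_dna_str(100)
  t3 <- paste0(substr(q, 1, 40), substr(q, 44, 100))
  got <- local_align(q, t3)
  want <- sw_oracle(q, t3)
  expect_equal(got$score, want$score)
  # random pairs against the oracle, and score symmetry
  for (i in 1:5) {
    q <- random_dna_str(60)
    t <- random_dna_str(70)
    got <- local_align(q, t)
    expect_equal(got$score, sw_oracle(q, t)$score)
    expect_equal(got$score, local_align(t, q)$score)
  }
  expect_error(local_align("", "ACGT"), "empty")
})

test_that("presence parsimony calls ancestral elements on 4/4 genomes only", {
  genomes <- c("g1", "g2", "g3", "g4")
  hits <- tibble::tibble(
    element_id = c(rep("e1", 4), rep("e2", 3)),
    sair_id = "s1",
    genome = c(genomes, genomes[1:3]),
    start = 0, end = 100, score = 50, evalue = 1e-10)
  calls <- call_ancestral_parsimony(hits, genomes)
  expect_true(calls$ancestral[calls$element_id == "e1"])
  expect_false(calls$ancestral[calls$element_id == "e2"])
  # a hit failing the E cutoff upstream never reaches the call: 3/4 remain
  filtered <- hits[!(hits$element_id == "e1" & hits$genome == "g4"), ]
  calls2 <- call_ancestral_parsimony(filtered, genomes)
  expect_false(calls2$ancestral[calls2$element_id == "e1"])
})

test_that("ancestral region calls enforce both alignment thresholds", {
  set.seed(91)
  core <- random_dna_str(150)
  pad <- function(s) paste0(random_dna_str(150), s, random_dna_str(150))
  sairs <- dplyr::bind_rows(lapply(c("ref", "o1", "o2"), function(g) {
    tibble::tibble(sair_id = "s1", subgenome = "LF", genome = g,
                   start = 0, end = 450, sequence = pad(core))
  }))
  regions <- tibble::tibble(sair_id = "s1", start = 150, end = 300)
  calls <- call_ancestral_regions(regions, sairs, reference = "ref")
  expect_true(calls$ancestral)
  # a 79-column alignment fails the 80-base minimum even at a perfect score
  short <- random_dna_str(79)
  sairs2 <- dplyr::bind_rows(
    tibble::tibble(sair_id = "s2", subgenome = "LF", genome = "ref",
                   start = 0, end = 79, sequence = short),
    tibble::tibble(sair_id = "s2", subgenome = "LF", genome = "o1",
                   start = 0, end = 79, sequence = short),
    tibble::tibble(sair_id = "s2", subgenome = "LF", genome = "o2",
                   start = 0, end = 79, sequence = short))
  regions2 <- tibble::tibble(sair_id = "s2", start = 0, end = 79)
  calls2 <- call_ancestral_regions(regions2, sairs2, reference = "ref")
  expect_false(calls2$ancestral)
})

test_that("densities are hits per kilobase and pool by length weighting", {
  sairs <- tibble::tibble(
    sair_id = c("a", "b"), subgenome = c("LF", "IF"),
    genome = "g1", start = 0, end = c(1000, 4000))
  hits <- tibble::tibble(sair_id = c("a", "a", "b"), genome = "g1")
  d <- re_density(hits, sairs)
  expect_equal(d$density[d$subgenome == "LF"], 2.0)
  expect_equal(d$density[d$subgenome == "IF"], 0.25)
  # zero hits give zero density
  d0 <- re_density(hits[0, ], sairs)
  expect_equal(d0$density, c(0, 0))
  # pooling two subgenomes equals the length-weighted mean of densities
  pooled <- re_density(dplyr::mutate(hits, pool = "all"),
                       dplyr::mutate(sairs, pool = "all"), by = "pool")
  w <- c(1000, 4000)
  expect_equal(pooled$density,
               sum(d$density[match(c("LF", "IF"), d$subgenome)] * w) / sum(w))
  expect_error(re_density(hits, dplyr::mutate(sairs, end = start)),
               "zero total")
})
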