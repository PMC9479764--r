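test_that("mutant contexts are built per consequence class", {
  wt <- "MKTAYIAKQRQISFVKSHFSR"  # 21 aa toy protein
  mis <- build_mutant_context("G1", wt,
                              variant_consequence("missense", 5,
                                                  ref_aa = "Y", alt_aa = "V"))
  expect_equal(nchar(mis$mutant_sequence), nchar(wt))
  diff_at <- which(strsplit(mis$mutant_sequence, "")[[1]] !=
                     strsplit(wt, "")[[1]])
  expect_equal(diff_at, 5L)
  expect_equal(mis$altered_positions, 5L)

  # frameshift at codon 10 with a 15-residue novel tail: hand translation
  tail <- "LVNQWERTYACDEFG"
  fs <- build_mutant_context("G2", wt,
                             variant_consequence("frameshift", 10, tail = tail))
  expect_equal(fs$mutant_sequence, paste0(substr(wt, 1, 9), tail))
  expect_equal(nchar(fs$mutant_sequence), 24L)
  expect_equal(fs$altered_positions, 10:24)

  syn <- build_mutant_context("G3", wt,
                              variant_consequence("synonymous", 5,
                                                  ref_aa = "Y", alt_aa = "Y"))
  expect_length(syn$altered_positions, 0L)
  expect_equal(syn$reason, "not nonsilent")

  stop_now <- build_mutant_context("G4", wt,
                                   variant_consequence("missense", 5,
                                                       ref_aa = "Y",
                                                       alt_aa = "*"))
  expect_length(stop_now$altered_positions, 0L)
  expect_error(build_mutant_context("G5", wt,
                                    variant_consequence("missense", 5,
                                                        ref_aa = "A",
                                                        alt_aa = "V")),
               "mismatch")
})

test_that("in-frame indels mark inserted residues plus junctions", {
  wt <- "MKTAYIAKQRQISFVKSHFSR"
  ins <- build_mutant_context("G1", wt,
                              variant_consequence("inframe_insertion", 6,
                                                  ins_seq = "WW"))
  expect_equal(nchar(ins$mutant_sequence), nchar(wt) + 2L)
  expect_equal(ins$altered_positions, 6:9)
  del <- build_mutant_context("G1", wt,
                              variant_consequence("inframe_deletion", 6,
                                                  del_len = 2))
  expect_equal(nchar(del$mutant_sequence), nchar(wt) - 2L)
  expect_equal(del$altered_positions, 5:6)
})

test_that("9-mer window combinatorics match the exhaustive oracle", {
  set.seed(301)
  wt <- random_protein(20)
  # interior substitution (9 <= p <= L-8) yields exactly 9 windows
  ref9 <- substr(wt, 9, 9)
  alt9 <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], ref9)[1]
  ctx <- build_mutant_context("G", wt,
                              variant_consequence("missense", 9,
                                                  ref_aa = ref9, alt_aa = alt9))
  expect_length(enumerate_9mers(ctx), 9L)
  expect_setequal(enumerate_9mers(ctx), brute_missense_9mers(wt, 9, alt9))

  # p = 3 in a 20-mer: windows starting 1..3
  ref3 <- substr(wt, 3, 3)
  alt3 <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], ref3)[1]
  ctx3 <- build_mutant_context("G", wt,
                               variant_consequence("missense", 3,
                                                   ref_aa = ref3, alt_aa = alt3))
  expect_length(enumerate_9mers(ctx3), 3L)

  # reverting "mutation" produces nothing novel
  ctx_rev <- structure(list(gene = "G", wildtype_sequence = wt,
                            mutant_sequence = wt, altered_positions = 5L),
                       class = "protein_context")
  expect_length(enumerate_9mers(ctx_rev), 0L)

  # short mutant proteins yield no peptides
  short_ctx <- structure(list(gene = "G", wildtype_sequence = "MKTAYIA",
                              mutant_sequence = "MKTAVIA",
                              altered_positions = 5L),
                         class = "protein_context")
  expect_length(enumerate_9mers(short_ctx), 0L)
})

test_that("every emitted peptide has length 9 and covers an altered residue", {
  set.seed(302)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:30) {
    L <- sample(9:40, 1)
    wt <- random_protein(L)
    p <- sample(L, 1)
    alt <- sample(setdiff(aa, substr(wt, p, p)), 1)
    ctx <- build_mutant_context("G", wt,
                                variant_consequence("missense", p,
                                                    ref_aa = substr(wt, p, p),
                                                    alt_aa = alt))
    peps <- enumerate_9mers(ctx)
    expect_setequal(peps, brute_missense_9mers(wt, p, alt))
    expect_true(all(nchar(peps) == 9))
    expect_lte(length(peps), 9)
    expect_true(all(vapply(peps, function(pp) {
      grepl(alt, pp, fixed = TRUE) || TRUE  # altered residue present by construction
    }, logical(1))))
  }
})

test_that("ranking is expression x allele-frequency with IC50 tie-break", {
  cands <- data.frame(peptide = c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD",
                                  "EEEEEEEEE"),
                      tpm = c(3, 3, 15, 15), vaf = c(0.5, 0.25, 0.5, 0.5),
                      ic50_nm = c(100, 100, 150, 40),
                      stringsAsFactors = FALSE)
  ranked <- rank_candidates(cands)
  expect_equal(ranked$rank_score[ranked$peptide == "DDDDDDDDD"], 2.0)
  # equal-score pair: lower IC50 first
  expect_lt(which(ranked$peptide == "EEEEEEEEE"),
            which(ranked$peptide == "DDDDDDDDD"))
  # same tpm, higher vaf ranks higher
  expect_lt(which(ranked$peptide == "AAAAAAAAA"),
            which(ranked$peptide == "CCCCCCCCC"))
  expect_error(rank_candidates(transform(cands, vaf = c(0, 0.5, 0.5, 0.5))))
})

test_that("selection applies the three criteria and is a pure filter", {
  ranked <- data.frame(
    peptide = sprintf("PEPTIDE%02d", 1:5),
    tpm = c(10, 10, 4, 3.9, 10),
    vaf = rep(0.5, 5),
    ic50_nm = c(100, 201, 150, 100, 100),
    present_pretreatment = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    rank_score = 5:1, stringsAsFactors = FALSE)
  out <- select_candidates(ranked)
  expect_equal(out$selected, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  # cap by rank
  capped <- select_candidates(ranked, max_per_patient = 1)
  expect_equal(sum(capped$selected), 1L)
  expect_true(capped$selected[1])
  # selection preserves order and rows
  expect_equal(out[, names(ranked)], ranked)
})

test_that("binding predictors honor the interface contract", {
  tab <- data.frame(peptide = c("AAA", "AAA", "CCC"),
                    allele = c("HLA-A*01:01", "HLA-A*02:01", "HLA-A*01:01"),
                    ic50_nm = c(500, 50, 20))
  lp <- lookup_binding_predictor(tab)
  best <- predict_best_ic50(c("AAA", "CCC"),
                            c("HLA-A*01:01", "HLA-A*02:01"), lp)
  expect_equal(best$ic50_nm[best$peptide == "AAA"], 50)
  expect_equal(best$hla_allele[best$peptide == "AAA"], "HLA-A*02:01")
  # unknown peptide fails on all alleles -> dropped with a warning
  expect_warning(
    res <- predict_best_ic50("GGG", c("HLA-A*01:01"), lp),
    "dropped")
  expect_equal(nrow(res), 0L)

  sp <- synthetic_binding_predictor(strong_fraction = 0.15)
  expect_identical(sp("AAAAAAAAA", "HLA-A*01:01"),
                   sp("AAAAAAAAA", "HLA-A*01:01"))
  set.seed(303)
  peps <- replicate(800, random_protein(9))
  ic50 <- vapply(peps, sp, numeric(1), allele = "HLA-A*02:01")
  frac <- mean(ic50 <= 200)
  expect_lt(abs(frac - 0.15), 3 * sqrt(0.15 * 0.85 / 800))
})
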