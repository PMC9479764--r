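make_callset <- function(caller, keys, type = "SNV", vaf = NULL) {
  if (length(keys) == 0L) {
    return(caller_callset(caller, data.frame(
      chrom = character(0), pos = integer(0), ref = character(0),
      alt = character(0), type = character(0), vaf = numeric(0))))
  }
  parts <- do.call(rbind, strsplit(keys, ":"))
  df <- data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                   ref = parts[, 3], alt = parts[, 4], type = type,
                   stringsAsFactors = FALSE)
  if (!is.null(vaf)) df$vaf <- vaf
  caller_callset(caller, df)
}

test_that("SNVs are retained when detected by at least 3 of the 4 callers", {
  v1 <- "chr1:100:A:G"; v2 <- "chr2:200:C:T"; v3 <- "chr3:300:G:A"
  sets <- list(make_callset("LoFreq", c(v1, v2)),
               make_callset("MuSE", c(v2, v3)),
               make_callset("Mutect2", c(v1, v2)),
               make_callset("Strelka2", c(v1, v3)))
  out <- consensus_snvs(sets)
  keys <- paste(out$chrom, out$pos, out$ref, out$alt, sep = ":")
  expect_setequal(keys, c(v1, v2))  # v3 has only 2 supporters
  expect_equal(out$n_support[keys == v1], 3L)
  expect_equal(out$supporting_callers[keys == v1], "LoFreq,Mutect2,Strelka2")

  all4 <- lapply(c("LoFreq", "MuSE", "Mutect2", "Strelka2"),
                 make_callset, keys = v1)
  expect_equal(consensus_snvs(all4)$n_support, 4L)
})

test_that("caller set validation catches missing and duplicate callers", {
  v <- "chr1:100:A:G"
  expect_error(consensus_snvs(list(make_callset("LoFreq", v),
                                   make_callset("MuSE", v),
                                   make_callset("Mutect2", v))),
               "configuration")
  expect_error(consensus_snvs(list(make_callset("LoFreq", v),
                                   make_callset("LoFreq", v),
                                   make_callset("Mutect2", v),
                                   make_callset("Strelka2", v))),
               "duplicate")
  expect_error(make_callset("MuSE", "chr1:100:AT:A", type = "INDEL"),
               "indels")
  expect_error(make_callset("LoFreq", c(v, v)), "duplicate")
})

test_that("indels are retained when detected by at least 2 of the 3 callers", {
  i1 <- "chr1:500:AT:A"; i2 <- "chr2:600:G:GCA"
  sets <- list(make_callset("LoFreq", i1, type = "INDEL"),
               make_callset("Mutect2", i2, type = "INDEL"),
               make_callset("Strelka2", c(i1, i2), type = "INDEL"))
  out <- consensus_indels(sets)
  expect_equal(nrow(out), 2L)

  only1 <- list(make_callset("LoFreq", character(0), type = "INDEL"),
                make_callset("Mutect2", i1, type = "INDEL"),
                make_callset("Strelka2", character(0), type = "INDEL"))
  expect_equal(nrow(consensus_indels(only1)), 0L)
})

test_that("consensus is monotone in support and idempotent on identical sets", {
  set.seed(201)
  keys <- sprintf("chr%d:%d:A:G", sample(1:22, 30, TRUE),
                  sample(1e6, 30))
  keys <- unique(keys)
  for (rep in 1:10) {
    supported <- lapply(c("LoFreq", "MuSE", "Mutect2", "Strelka2"),
                        function(cl) make_callset(cl, keys[runif(length(keys)) < 0.7]))
    base <- consensus_snvs(supported)
    # add one more supporting caller for a random variant
    k <- sample(keys, 1)
    grown <- supported
    for (j in seq_along(grown)) {
      if (!k %in% grown[[j]]$variants$key) {
        v <- grown[[j]]$variants
        parts <- strsplit(k, ":")[[1]]
        v <- rbind(v[, c("chrom", "pos", "ref", "alt", "type")],
                   data.frame(chrom = parts[1], pos = as.integer(parts[2]),
                              ref = parts[3], alt = parts[4], type = "SNV"))
        grown[[j]] <- caller_callset(grown[[j]]$caller, v)
        break
      }
    }
    grown_keys <- with(consensus_snvs(grown),
                       paste(chrom, pos, ref, alt, sep = ":"))
    base_keys <- with(base, paste(chrom, pos, ref, alt, sep = ":"))
    expect_true(all(base_keys %in% grown_keys))
  }

  same <- lapply(c("LoFreq", "MuSE", "Mutect2", "Strelka2"),
                 make_callset, keys = keys)
  out <- consensus_snvs(same)
  expect_setequal(with(out, paste(chrom, pos, ref, alt, sep = ":")), keys)
  expect_true(all(out$n_support == 4L))
})

test_that("VAF comes from Mutect2 when available, else the supporter mean", {
  v <- "chr1:100:A:G"
  sets <- list(make_callset("LoFreq", v, vaf = 0.30),
               make_callset("MuSE", v, vaf = 0.40),
               make_callset("Mutect2", v, vaf = 0.25),
               make_callset("Strelka2", character(0)))
  expect_equal(consensus_snvs(sets)$vaf, 0.25)

  sets2 <- list(make_callset("LoFreq", v, vaf = 0.30),
                make_callset("MuSE", v, vaf = 0.40),
                make_callset("Strelka2", v, vaf = 0.20),
                make_callset("Mutect2", character(0)))
  expect_equal(consensus_snvs(sets2)$vaf, 0.30)
})

test_that("padded indel representations normalize to one key", {
  a <- normalize_variant(100L, "CAG", "CTAG")   # padded insertion
  b <- normalize_variant(99L, "TCA", "TCTA")    # differently padded
  expect_equal(a, b)
  expect_equal(a$pos, 100L)
  expect_equal(a$ref, "C")
  expect_equal(a$alt, "CT")
  # SNVs pass through untouched
  expect_equal(normalize_variant(50L, "A", "G"),
               list(pos = 50L, ref = "A", alt = "G"))
})

test_that("expression transform is log2(TPM + 1)", {
  expect_equal(log2_tpm(0), 0)
  expect_equal(log2_tpm(3), 2)
  expect_equal(log2_tpm(7), 3)
  expect_error(log2_tpm(-1))
})
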