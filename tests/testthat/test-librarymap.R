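# Exact antisense siRNA-to-transcript matching and the four-siRNA
# single-gene well filter.

dss <- function(x) Biostrings::DNAStringSet(x)
rc_of <- function(x) as.character(Biostrings::reverseComplement(
  Biostrings::DNAString(x)))

test_that("an siRNA maps via its reverse complement, not its own sequence", {
  set.seed(101)
  target <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  sub <- substr(target, 11, 31)
  sirna <- rc_of(sub)
  tx <- dss(c("T1 gene=GA" = target))
  si <- dss(setNames(sirna, "s1 well=W1 gene=GA"))
  m <- map_sirnas(si, tx)
  expect_equal(m$genes[[1]], "GA")

  # the sense-strand sequence itself must NOT map (antisense convention)
  si_sense <- dss(setNames(sub, "s2 well=W1 gene=GA"))
  # skip the trivially palindromic case
  if (rc_of(sub) != sub) {
    m2 <- map_sirnas(si_sense, tx)
    expect_length(m2$genes[[1]], 0)
  }
})

test_that("an siRNA matching two genes carries both in its gene set", {
  set.seed(5)
  core <- paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = "")
  pad <- function() paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  tx <- dss(c("T1 gene=GA" = paste0(pad(), core, pad()),
              "T2 gene=GB" = paste0(pad(), core, pad())))
  si <- dss(setNames(rc_of(core), "s1 well=W1 gene=GA"))
  m <- map_sirnas(si, tx)
  expect_setequal(m$genes[[1]], c("GA", "GB"))
})

test_that("a clean synthetic library maps each siRNA to its truth gene only", {
  lib <- simulate_library(40, transcriptome_size = 55, offtarget_rate = 0,
                          seed = 19)
  m <- map_sirnas(lib$sirnas, lib$transcripts)
  expect_true(all(lengths(m$genes) == 1))
  expect_equal(unlist(m$genes), m$gene_claimed, ignore_attr = TRUE)
})

test_that("malformed libraries are rejected", {
  tx <- dss(c("T1 gene=GA" = paste(rep("ACGT", 20), collapse = "")))
  dup <- dss(setNames(c("ACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTA"),
                      c("s1 well=W1 gene=GA", "s1 well=W1 gene=GA")))
  expect_error(map_sirnas(dup, tx), "duplicate")
  expect_error(map_sirnas(dss(character()), tx), "empty")
})

test_that("the well filter implements the stated status rules", {
  mk <- function(genes_list) {
    tibble::tibble(sirna_id = sprintf("s%d", seq_along(genes_list)),
                   well_key = "W1", gene_claimed = "GA",
                   n_transcripts = lengths(genes_list), genes = genes_list)
  }
  expect_equal(filter_wells(mk(list("GA", "GA", "GA", "GA")))$status, "pass")
  expect_equal(filter_wells(mk(list("GA", "GA", "GA", character())))$status,
               "fail_unmapped")
  expect_equal(filter_wells(mk(list(c("GA", "GB"), c("GA", "GB"),
                                    c("GA", "GB"), c("GA", "GB"))))$status,
               "fail_multi")
  expect_equal(filter_wells(mk(list("GA", "GA", "GA", "GB")))$status,
               "fail_discordant")
  # individually ambiguous but a unique shared gene passes, unless strict
  mixed <- mk(list(c("GA", "GB"), "GA", "GA", "GA"))
  expect_equal(filter_wells(mixed)$status, "pass")
  expect_equal(filter_wells(mixed)$gene, "GA")
  expect_equal(filter_wells(mixed, strict = TRUE)$status, "fail_multi")
})

test_that("the filter is order-independent and matches generator truth", {
  lib <- simulate_library(200, transcriptome_size = 230, offtarget_rate = 0.3,
                          seed = 23)
  m <- map_sirnas(lib$sirnas, lib$transcripts)
  f1 <- filter_wells(m)
  f2 <- filter_wells(m[sample(nrow(m)), ])
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  joined <- dplyr::inner_join(as.data.frame(f1), lib$truth, by = "well_key")
  expect_equal(joined$status, joined$expected_status)
})

test_that("GMT files round-trip", {
  sets <- list(cycle = c("CDK1", "PLK1", "KIF11"),
               histone = c("CASP8AP2", "NPAT", "HINFP"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets)
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("only_one_field", bad)
  expect_error(read_gmt(bad), "fewer than 3")
})
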