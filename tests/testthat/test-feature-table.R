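# build a small raw annotation table on disk
write_toy_annotations <- function(path) {
  tab <- data.frame(
    locus_id = c("chr1:100:A:G", "chr1:200:C:T", "chr1:300:G:A"),
    GerpN = c("2.1", "NA", "-0.5"),
    bStatistic = c("800", "650", "abc"),
    Consequence = c("STOP_GAINED", "INTRONIC", NA),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_spec <- data.frame(
  name = c("GerpN", "bStatistic", "Consequence"),
  kind = c("numeric", "numeric", "categorical"),
  stringsAsFactors = FALSE)

test_that("the canonical header minus the three exclusion lists leaves 70 features", {
  nm <- ase_feature_names()
  excl <- ase_feature_exclusions()
  expect_length(nm, 109)
  expect_equal(lengths(excl, use.names = FALSE), c(12, 16, 11))
  expect_true(all(unlist(excl) %in% nm))
  expect_length(setdiff(nm, unlist(excl)), 70)
  # features highlighted as top contributors are among the retained 70
  retained <- setdiff(nm, unlist(excl))
  expect_true(all(c("GerpN", "bStatistic", "Dist2Mutation", "cDNApos",
                    "minDistTSE", "cHmmReprPCWk", "cHmmQuies", "pLI_score")
                  %in% retained))
})

test_that("annotation loading parses kinds, flags missing, rejects unknowns", {
  path <- tempfile(fileext = ".tsv")
  write_toy_annotations(path)
  fm <- load_annotations(path, toy_spec)
  expect_equal(dim(fm), c(3L, 3L))
  expect_identical(fm$row_ids, c("chr1:100:A:G", "chr1:200:C:T", "chr1:300:G:A"))
  expect_true(is.na(fm$data$GerpN[2]))        # literal NA cell
  expect_true(is.na(fm$data$bStatistic[3]))   # unparseable numeric cell
  expect_true(is.na(fm$data$Consequence[3]))

  bad_spec <- toy_spec[1:2, ]
  expect_error(load_annotations(path, bad_spec), "Consequence")
})

test_that("duplicate row ids are rejected", {
  path <- tempfile(fileext = ".tsv")
  tab <- utils::read.delim(write_toy_annotations(path), colClasses = "character")
  tab$locus_id[2] <- tab$locus_id[1]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_annotations(path, toy_spec), "duplicate")
})

test_that("exclusion handling: identity, order preservation, unknown names", {
  truth <- rep(c(TRUE, FALSE), 10)
  fm <- simulate_feature_matrix(truth, feature_sim_config(n_features_numeric = 10, seed = 4))
  expect_identical(suppressMessages(apply_exclusions(fm, list()))$data, fm$data)
  out <- suppressMessages(apply_exclusions(fm, list(manual = c("num02", "num05", "num09"))))
  expect_identical(names(out$data), setdiff(names(fm$data), c("num02", "num05", "num09")))
  expect_equal(ncol(out$data), 7)
  expect_error(apply_exclusions(fm, list(manual = "nope")), "nope")
  # idempotent on its own output
  again <- suppressMessages(apply_exclusions(out, list()))
  expect_identical(again$data, out$data)
})

test_that("imputation and encoding produce a finite numeric matrix", {
  df <- data.frame(x = c(1, NA, 3, NA), cat = c("B", "A", NA, "B"),
                   stringsAsFactors = FALSE)
  specs <- data.frame(name = c("x", "cat"), kind = c("numeric", "categorical"),
                      imputation_default = c("0.0", NA), stringsAsFactors = FALSE)
  fm <- feature_matrix(df, sprintf("v%d", 1:4), specs)
  enc <- impute_and_encode(fm)
  expect_equal(enc$data$x, c(1, 0, 3, 0))          # configured default fill
  expect_equal(enc$data$cat, c(1, 0, 1, 1))        # alphabetical codes; NA -> modal level B
  expect_false(anyNA(as.matrix(enc)))
  expect_true(all(is.finite(as.matrix(enc))))
  # encoding is a pure function of the data (stable across runs)
  expect_identical(impute_and_encode(fm)$encoders, enc$encoders)
})

test_that("apply-time encoding reuses training dictionaries and reserves an unknown code", {
  tr <- data.frame(cat = c("A", "B", "A"), stringsAsFactors = FALSE)
  ap <- data.frame(cat = c("B", "C", "A"), stringsAsFactors = FALSE)
  specs <- data.frame(name = "cat", kind = "categorical", stringsAsFactors = FALSE)
  enc_tr <- impute_and_encode(feature_matrix(tr, sprintf("t%d", 1:3), specs))
  expect_warning(
    enc_ap <- impute_and_encode(feature_matrix(ap, sprintf("a%d", 1:3), specs),
                                encoders = enc_tr$encoders),
    "unseen")
  expect_equal(enc_ap$data$cat, c(1, 2, 0))  # C -> reserved code 2
  expect_equal(nrow(enc_ap$data), 3)
})

test_that("an encoded matrix round-trips through its TSV + sidecar files", {
  truth <- rep(c(TRUE, FALSE), 15)
  fm <- impute_and_encode(simulate_feature_matrix(
    truth, feature_sim_config(n_features_numeric = 3, n_features_categorical = 1,
                              missing_rate = 0.2, seed = 8)))
  prefix <- tempfile()
  write_feature_matrix(fm, prefix)
  back <- read_feature_matrix(prefix)
  expect_equal(back$data, fm$data)
  expect_identical(back$row_ids, fm$row_ids)
  expect_equal(back$encoders$categories, fm$encoders$categories)
  expect_equal(unlist(back$encoders$imputation), unlist(fm$encoders$imputation))
})
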