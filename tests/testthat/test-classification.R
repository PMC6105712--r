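# Build a kdtc_fc directly from a log2fc matrix (genes x "cond@tp" columns)
fc_from_matrix <- function(log2fc, timepoints = default_timepoints()) {
  parts <- strsplit(colnames(log2fc), "@", fixed = TRUE)
  structure(list(log2fc = log2fc,
                 contrasts = data.frame(
                   condition = vapply(parts, `[`, "", 1L),
                   timepoint = vapply(parts, `[`, "", 2L),
                   stringsAsFactors = FALSE),
                 timepoints = timepoints, reference = "siCTR"),
            class = "kdtc_fc")
}

test_that("affected calls use the inclusive magnitude cutoff", {
  l2 <- matrix(c(1.0, -0.5, log2(1.8), -log2(1.8), 0, 0.84),
               ncol = 1, dimnames = list(paste0("G", 1:6), "siCBP@T48"))
  st <- flag_affected(fc_from_matrix(l2), 1.8)
  dir <- st$conditions$siCBP$direction[, "T48"]
  expect_identical(unname(dir),
                   c("up", "none", "up", "down", "none", "none"))
  expect_error(flag_affected(fc_from_matrix(l2), 1), class = "kdtc_bad_cutoff")
})

test_that("transfection artifacts are excluded at any shared timepoint", {
  sheet <- full_sheet()
  values <- design_matrix(sheet, overrides = list(
    list(gene = "GA", condition = "NT", timepoint = "T48", value = 9),     # fold 2.0
    list(gene = "GB", condition = "NT", timepoint = "T48", value = 8.7),   # fold ~1.62
    list(gene = "GB", condition = "NT", timepoint = "T72", value = 8.766)))# fold ~1.7
  fc_nt <- compute_fold_changes(values, sheet, conditions = "NT")
  expect_identical(exclude_transfection_artifacts(fc_nt, 1.8), "GA")
  # NT identical to siCTR everywhere -> empty set
  flat <- design_matrix(sheet)
  fc0 <- compute_fold_changes(flat, sheet, conditions = "NT")
  expect_length(exclude_transfection_artifacts(fc0, 1.8), 0)
  # NT absent -> skipped with a warning
  expect_warning(out <- exclude_transfection_artifacts(NULL, 1.8),
                 class = "kdtc_no_nt")
  expect_length(out, 0)
})

test_that("specificity classification matches a truth-table oracle", {
  # enumerate every combination of per-timepoint directions for two factors
  # over two timepoints: 3^4 = 81 genes
  dirs <- c(-1, 0, 1)
  combos <- expand.grid(c1 = dirs, c2 = dirs, p1 = dirs, p2 = dirs)
  n <- nrow(combos)
  eff <- log2(2.5)
  genes <- sprintf("G%02d", seq_len(n))
  mk <- function(a, b) { # a, b in {-1,0,1}; distinct |fc| so the max is unique
    cbind(a * eff, b * eff * 1.1)
  }
  cbp <- mk(combos$c1, combos$c2)
  p300 <- mk(combos$p1, combos$p2)
  l2 <- cbind(cbp, p300)
  dimnames(l2) <- list(genes, c("siCBP@T48", "siCBP@T72",
                                "siP300@T48", "siP300@T72"))
  cl <- classify_specificity(flag_affected(fc_from_matrix(l2), 1.8))

  oracle <- function(c1, c2, p1, p2) {
    agg <- function(x1, x2) { # direction at max |fc|, T72 effect is larger
      if (x1 == 0 && x2 == 0) return("none")
      if (x2 != 0) (if (x2 > 0) "up" else "down")
      else (if (x1 > 0) "up" else "down")
    }
    a <- agg(c1, c2); b <- agg(p1, p2)
    if (a == "none" && b == "none") return("unaffected")
    if (a != "none" && b == "none") return(paste0("CBP_specific_", a))
    if (a == "none" && b != "none") return(paste0("P300_specific_", b))
    if (a == b) paste0("common_", a) else "opposite"
  }
  want <- mapply(oracle, combos$c1, combos$c2, combos$p1, combos$p2)
  expect_identical(cl$category, unname(want))
  # mixed-within-factor flag fires iff a factor has both signs
  expect_identical(cl$cbp_mixed, combos$c1 * combos$c2 < 0)
  # spec worked example: down by CBP at T48 only and down by P300 at T72 only
  g <- genes[combos$c1 == -1 & combos$c2 == 0 & combos$p1 == 0 & combos$p2 == -1]
  expect_identical(cl$category[cl$gene_id == g], "common_down")
})

test_that("swapping the factors swaps specific categories, fixes common/opposite", {
  sim <- generate_dataset(small_config(), seed = 21)
  fc <- compute_fold_changes(sim$values, sim$sheet,
                             conditions = c("siCBP", "siP300"))
  st <- flag_affected(fc, 1.8)
  a <- classify_specificity(st)
  b <- classify_specificity(st, cbp = "siP300", p300 = "siCBP")
  swap <- c(CBP_specific_up = "P300_specific_up",
            CBP_specific_down = "P300_specific_down",
            P300_specific_up = "CBP_specific_up",
            P300_specific_down = "CBP_specific_down",
            common_up = "common_up", common_down = "common_down",
            opposite = "opposite", unaffected = "unaffected")
  expect_identical(unname(swap[a$category]), b$category)
})

test_that("raising the cutoff never grows any affected set", {
  sim <- generate_dataset(small_config(), seed = 31)
  fc <- compute_fold_changes(sim$values, sim$sheet,
                             conditions = c("siCBP", "siP300", "siCBP_P300"))
  sets_at <- function(cutoff) {
    st <- flag_affected(fc, cutoff)
    lapply(st$conditions, function(cs) {
      rownames(cs$direction)[rowSums(cs$direction != "none") > 0]
    })
  }
  s18 <- sets_at(1.8)
  s25 <- sets_at(2.5)
  for (cond in names(s18)) {
    expect_true(all(s25[[cond]] %in% s18[[cond]]))
  }
})

test_that("double-only genes are affected in the double knockdown alone", {
  sheet <- full_sheet()
  values <- design_matrix(sheet, genes = c("GA", "GB", "GC"), overrides = list(
    list(gene = "GA", condition = "siCBP_P300", timepoint = "T72", value = 6.5),
    list(gene = "GB", condition = "siCBP", timepoint = "T72", value = 6.5),
    list(gene = "GB", condition = "siCBP_P300", timepoint = "T72", value = 6.5)))
  cl <- classify_dataset(list(values = values, sheet = sheet), cutoff = 1.8)
  expect_identical(cl$category[cl$gene_id == "GA"], "double_only_down")
  expect_identical(cl$category[cl$gene_id == "GB"], "CBP_specific_down")
  expect_identical(cl$category[cl$gene_id == "GC"], "unaffected")
})

test_that("noiseless generation recovers all 30 planted redundant genes", {
  sim <- generate_dataset(small_config(noise_sd = 0), seed = 8)
  cl <- classify_dataset(sim)
  want <- sim$truth$gene_id[sim$truth$class == "redundant_double_only"]
  got <- cl$gene_id[grepl("^double_only", cl$category)]
  expect_setequal(got, want)
  expect_length(got, 30)
})

test_that("category partition and percentage arithmetic hold", {
  sim <- generate_dataset(small_config(), seed = 41)
  cl <- classify_dataset(sim)
  # partition: every gene exactly one category; excluded genes nowhere else
  expect_identical(nrow(cl), 2000L)
  expect_true(all(cl$category[cl$gene_id %in% attr(cl, "excluded")] == "excluded"))
  s <- summarize_categories(cl)
  expect_equal(sum(s$counts), s$union)
  expect_equal(sum(s$percent), 100, tolerance = 1e-9)
  expect_true(abs(sum(s$percent_rounded) - 100) <= 1)
  # per-timepoint table totals never exceed the non-excluded universe
  ptc <- s$per_timepoint
  expect_true(all(rowSums(ptc[, -1]) <= 2000 - length(attr(cl, "excluded"))))
})

test_that("published aggregated counts reproduce the printed percentages", {
  s <- summarize_categories(c(P300_specific = 1617, CBP_specific = 1048,
                              common = 623, opposite = 76))
  expect_identical(unname(s$percent_rounded), c(48, 31, 19, 2))
  expect_identical(unname(s$union), 3364)
  s2 <- summarize_categories(c(P300_specific = 10, CBP_specific = 10,
                               common = 0, opposite = 0))
  expect_identical(unname(s2$percent_rounded), c(50, 50, 0, 0))
})
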