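test_that("program definition contrasts later timepoints against T0 in control", {
  sheet <- full_sheet()
  values <- design_matrix(sheet, genes = c("GA", "GB"))
  for (tp in c("T72", "T96")) {
    cols <- sheet$sample_id[sheet$condition == "siCTR" & sheet$timepoint == tp]
    values["GA", cols] <- 9.5
  }
  prog <- define_program(values, sheet, cutoff = 1.8)
  expect_setequal(prog$sets$T72$activated, "GA")
  expect_length(prog$sets$T48$activated, 0)
  expect_length(prog$sets$T72$repressed, 0)
  expect_true(all(vapply(prog$sets, function(s)
    length(intersect(s$activated, s$repressed)) == 0, logical(1))))
  no_t0 <- sheet[!(sheet$condition == "siCTR" & sheet$timepoint == "T0"), ]
  attr(no_t0, "timepoints") <- attr(sheet, "timepoints")
  class(no_t0) <- class(sheet)
  expect_error(define_program(values[, no_t0$sample_id], no_t0, 1.8),
               class = "kdtc_missing_t0")
})

test_that("noiseless planted program genes are recovered exactly", {
  sim <- generate_dataset(small_config(noise_sd = 0), seed = 2)
  prog <- define_program(sim$values, sim$sheet, cutoff = 1.8)
  act <- sim$truth$gene_id[sim$truth$program_activated]
  rep_ <- sim$truth$gene_id[sim$truth$program_repressed]
  for (tp in c("T48", "T72", "T96")) {
    expect_setequal(prog$sets[[tp]]$activated, act)
    expect_setequal(prog$sets[[tp]]$repressed, rep_)
  }
})

test_that("planted disruption fraction is reported exactly at sigma = 0", {
  cfg <- small_config(noise_sd = 0, program_disrupted_fraction = 0.3)
  sim <- generate_dataset(cfg, seed = 4)
  fc <- compute_fold_changes(sim$values, sim$sheet,
                             conditions = c("siCBP", "siP300", "siCBP_P300"))
  status <- flag_affected(fc, 1.8)
  prog <- define_program(sim$values, sim$sheet, cutoff = 1.8)
  rows <- program_disruption(prog, status, "siCBP")
  expect_true(all(rows$fraction[rows$direction == "activated"] == 0.3))
  expect_true(all(rows$fraction[rows$direction == "repressed"] == 0.3))
})

test_that("recapitulation and redundancy follow naive set arithmetic", {
  mk_status <- function(sets) {
    # sets: list(cond -> list(tp -> list(up=..., down=...)))
    genes <- sort(unique(unlist(sets)))
    conds <- lapply(sets, function(tps) {
      dir <- matrix("none", length(genes), length(tps),
                    dimnames = list(genes, names(tps)))
      l2 <- matrix(0, length(genes), length(tps),
                   dimnames = list(genes, names(tps)))
      for (tp in names(tps)) {
        dir[genes %in% tps[[tp]]$up, tp] <- "up"
        dir[genes %in% tps[[tp]]$down, tp] <- "down"
      }
      list(direction = dir, log2fc = l2)
    })
    structure(list(conditions = conds, gene_ids = genes,
                   timepoints = names(sets[[1]]), cutoff = 1.8),
              class = "kdtc_status")
  }
  st <- mk_status(list(
    siCBP = list(T48 = list(up = character(0), down = c("a", "b", "c", "d"))),
    siP300 = list(T48 = list(up = character(0), down = character(0))),
    siCBP_P300 = list(T48 = list(up = character(0), down = c("a", "b", "x")))))
  rows <- recapitulation(st)
  rec <- rows[rows$analysis == "recapitulation" & rows$factor == "siCBP" &
                rows$direction == "down", ]
  expect_equal(rec$fraction, 0.5)
  red <- rows[rows$analysis == "redundancy" & rows$direction == "down", ]
  expect_equal(red$fraction, 1 / 3)
  # empty denominators are absent fractions
  up <- rows[rows$direction == "up", ]
  expect_true(all(is.na(up$fraction)))

  # identical sets: full recapitulation, zero redundancy
  st2 <- mk_status(list(
    siCBP = list(T48 = list(up = c("u1", "u2"), down = character(0))),
    siP300 = list(T48 = list(up = character(0), down = character(0))),
    siCBP_P300 = list(T48 = list(up = c("u1", "u2"), down = character(0)))))
  rows2 <- recapitulation(st2)
  expect_equal(rows2$fraction[rows2$analysis == "recapitulation" &
                                rows2$factor == "siCBP" &
                                rows2$direction == "up"], 1)
  expect_equal(rows2$fraction[rows2$analysis == "redundancy" &
                                rows2$direction == "up"], 0)
})

test_that("all overlap fractions are bounded and numerators fit denominators", {
  sim <- generate_dataset(small_config(program_disrupted_fraction = 0.2),
                          seed = 12)
  fc <- compute_fold_changes(sim$values, sim$sheet,
                             conditions = c("siCBP", "siP300", "siCBP_P300"))
  status <- flag_affected(fc, 1.8)
  prog <- define_program(sim$values, sim$sheet, cutoff = 1.8)
  rows <- rbind(program_disruption(prog, status, "siCBP"),
                program_disruption(prog, status, "siP300"),
                recapitulation(status))
  expect_true(all(rows$numerator <= rows$denominator))
  ok <- !is.na(rows$fraction)
  expect_true(all(rows$fraction[ok] >= 0 & rows$fraction[ok] <= 1))
})
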