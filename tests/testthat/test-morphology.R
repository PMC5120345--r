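make_specimen <- function(id = "s1", fl = rep(30, 5), arrangement = "tight",
                          color = "whole_dark", middle_lobe = "none_obvious",
                          terminal_lobe = "large_fused", ...) {
  data.frame(id = id, fl1 = fl[1], fl2 = fl[2], fl3 = fl[3], fl4 = fl[4],
             fl5 = fl[5], arrangement = arrangement, color = color,
             middle_lobe = middle_lobe, terminal_lobe = terminal_lobe,
             ..., stringsAsFactors = FALSE)
}

test_that("mean filament length is the plain 5-point average", {
  expect_equal(mean_filament_length(c(50, 50, 50, 50, 50)), 50)
  expect_equal(mean_filament_length(c(30, 40, 50, 60, 70)), 50)
  expect_equal(mean_filament_length(c(10, 10, 10, 10, 100)), 28)
  expect_error(mean_filament_length(c(10, 10, 10, 10)), "exactly 5")
  expect_error(mean_filament_length(c(10, 10, -1, 10, 10)), "positive")
  df <- rbind(make_specimen("a", fl = c(30, 40, 50, 60, 70)),
              make_specimen("b", fl = rep(20, 5)))
  expect_equal(mean_filament_length(df), c(50, 20))
})

test_that("the >70 mm screen is a strict inequality", {
  expect_equal(size_screen(75), "MANTA_LIKELY")
  expect_equal(size_screen(50), "NOT_FLAGGED")
  expect_equal(size_screen(70), "NOT_FLAGGED")
  expect_equal(size_screen(70 + 1e-9), "MANTA_LIKELY")
  expect_error(size_screen(0), "positive")
})

test_that("the three-step rule reproduces the canonical decisions", {
  # step 1: non-fused terminal lobes are weeded out
  r <- three_step_classify(make_specimen(terminal_lobe = "sharp_apex",
                                         middle_lobe = "veins"))
  expect_equal(r$call, "OTHER_MOBULA")
  expect_equal(r$step, 1L)
  expect_false(r$low_confidence)

  # step 2: variegated gills (light base + cilia) are Mo. tarapacana
  r <- three_step_classify(make_specimen(color = "light_base",
                                         middle_lobe = "cilia"))
  expect_equal(r$call, "MOBULA_TARAPACANA")
  expect_equal(r$step, 2L)
  expect_false(r$low_confidence)

  # step 3: finger-like projections identify Manta
  r <- three_step_classify(make_specimen(middle_lobe = "finger_like"))
  expect_equal(r$call, "MANTA")
  expect_false(r$low_confidence)

  # step-3 fallbacks are flagged, never abstentions
  r <- three_step_classify(make_specimen(color = "whole_dark",
                                         middle_lobe = "none_obvious"))
  expect_equal(r$call, "MANTA")
  expect_true(r$low_confidence)
  r <- three_step_classify(make_specimen(color = "light_base",
                                         middle_lobe = "oval"))
  expect_equal(r$call, "MOBULA_TARAPACANA")
  expect_true(r$low_confidence)
})

test_that("the three-step rule is total over the whole trait space", {
  lv <- trait_levels()
  grid <- expand.grid(arrangement = lv$arrangement, color = lv$color,
                      middle_lobe = lv$middle_lobe,
                      terminal_lobe = lv$terminal_lobe,
                      stringsAsFactors = FALSE)
  df <- data.frame(id = paste0("g", seq_len(nrow(grid))),
                   fl1 = 30, fl2 = 30, fl3 = 30, fl4 = 30, fl5 = 30,
                   grid, stringsAsFactors = FALSE)
  r <- three_step_classify(df)
  expect_equal(nrow(r), 3 * 4 * 5 * 3)
  expect_true(all(r$call %in% c("MANTA", "MOBULA_TARAPACANA",
                                "OTHER_MOBULA")))
  expect_false(anyNA(r$call))
})

test_that("three-step rates on synthetic single-species batches", {
  manta <- generate_specimen_set(
    generator_config(seed = 5, species_counts = c(Manta_birostris = 800)))
  r <- three_step_classify(manta$specimens)
  expect_gte(mean(r$call == "MANTA"), 0.75)

  jap <- generate_specimen_set(
    generator_config(seed = 6, species_counts = c(Mobula_japanica = 800)))
  r <- three_step_classify(jap$specimens)
  expect_gte(mean(r$call == "OTHER_MOBULA"), 0.90)
})

test_that("specimen CSV round-trips and validation catches bad rows", {
  cfg <- small_config(seed = 3)
  ss <- generate_specimen_set(cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_specimens(ss$specimens, f)
  back <- read_specimens(f)
  expect_equal(back$id, ss$specimens$id)
  expect_equal(back$middle_lobe, ss$specimens$middle_lobe)
  expect_equal(back$fl3, ss$specimens$fl3, tolerance = 1e-9)

  bad <- make_specimen(arrangement = "floppy")
  expect_error(validate_specimens(bad), "invalid arrangement.*floppy")
  bad <- make_specimen(fl = c(10, 10, 0, 10, 10))
  expect_error(validate_specimens(bad), "positive")
  bad <- rbind(make_specimen("x"), make_specimen("x"))
  expect_error(validate_specimens(bad), "duplicate")
  expect_error(validate_specimens(make_specimen()[-2]), "missing")
})
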