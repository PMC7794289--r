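test_that("vessel tree generation is deterministic and respects the effect switch", {
  cfg <- small_config(small_vessel_effect = 1)
  a <- generate_vessel_tree(cfg, "AD", seed = 42)
  b <- generate_vessel_tree(cfg, "AD", seed = 42)
  expect_identical(a$pixels, b$pixels)
  # effect off: AD and NC draws are pixel-identical under the same seed
  nc <- generate_vessel_tree(cfg, "NC", seed = 42)
  expect_identical(a$pixels, nc$pixels)
  expect_true(all(a$pixels >= 0 & a$pixels <= 1))
})

test_that("small-vessel effect thins the AD small-vessel bed, not the majors", {
  cfg <- small_config(small_vessel_effect = 0.5)
  fg <- function(group) {
    vapply(1:100, function(i) {
      m <- generate_vessel_tree(cfg, group, seed = i)
      c(m$meta$n_foreground, m$meta$n_thin)
    }, numeric(2))
  }
  ad <- fg("AD"); nc <- fg("NC")
  expect_lt(mean(ad[1, ]), mean(nc[1, ]))   # total foreground shrinks
  expect_lt(mean(ad[2, ]), mean(nc[2, ]))   # thin-vessel pixels shrink
})

test_that("thin-vessel count is non-increasing as the effect strengthens", {
  thins <- vapply(c(1, 0.75, 0.5, 0.25), function(e) {
    cfg <- small_config(small_vessel_effect = e)
    mean(vapply(1:100, function(i) {
      generate_vessel_tree(cfg, "AD", seed = i)$meta$n_thin
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(thins) <= 0))
})

test_that("zero branch depth yields only major branches", {
  cfg <- small_config(branch_depth = 0)
  m <- generate_vessel_tree(cfg, "NC", seed = 3)
  expect_identical(m$meta$n_thin, 0L)
  expect_gt(m$meta$n_foreground, 0)
})

test_that("fundus rendering stays in range and encodes the fault taxonomy", {
  v <- generate_vessel_tree(small_config(), "NC", seed = 1)
  clean <- render_fundus(v, "none")
  expect_equal(clean$quality_label, "sufficient")
  expect_true(all(clean$pixels >= 0 & clean$pixels <= 1))
  for (f in c("exposure", "focus", "composition", "artifact")) {
    img <- render_fundus(v, f, severity = 1, seed = 11)
    expect_equal(img$quality_label, "insufficient")
    expect_true(all(img$pixels >= 0 & img$pixels <= 1))
  }
  expect_error(fundus_image(clean$pixels, fault = "smudge"))
})

test_that("defocus strictly reduces gradient energy", {
  v <- generate_vessel_tree(small_config(), "NC", seed = 2)
  sharp <- render_fundus(v, "none")
  blurred <- render_fundus(v, "focus", severity = 1, seed = 5)
  expect_lt(grad_energy(blurred$pixels), grad_energy(sharp$pixels))
})

test_that("full-severity exposure clips at least a quarter of the pixels", {
  v <- generate_vessel_tree(small_config(), "NC", seed = 4)
  for (i in 1:20) {
    img <- render_fundus(v, "exposure", severity = 1, seed = i)
    expect_gte(mean(img$pixels == 0 | img$pixels == 1), 0.25)
  }
})

test_that("cohort generation mirrors the case/control layout and matching keys", {
  cfg <- simulation_config(image_size = 32, n_ad = 6, n_controls_per_ad = 5,
                           branch_depth = 1)
  co <- generate_cohort(cfg, seed = 9)
  tab <- co$table
  expect_equal(sum(tab$diagnosis == "AD"), 6)
  expect_equal(sum(tab$diagnosis == "NC"), 30)
  expect_false(anyDuplicated(tab$subject_id) > 0)
  expect_setequal(tab$image_id, names(co$maps))
  # every AD row has n_controls_per_ad exact (age, sex, eye) NC candidates
  key <- paste(tab$age, tab$sex, tab$eye)
  for (i in which(tab$diagnosis == "AD")) {
    expect_gte(sum(key[tab$diagnosis == "NC"] == key[i]), 5)
  }
  # ages bracket the configured uniform range
  expect_true(all(tab$age >= 55 & tab$age <= 75))
})

test_that("image and table round-trips preserve content", {
  cfg <- simulation_config(image_size = 32, n_ad = 2, n_controls_per_ad = 1,
                           branch_depth = 1)
  co <- generate_cohort(cfg, seed = 5)
  png_path <- withr::local_tempfile(fileext = ".png")
  write_image_png(co$maps[[1]], png_path)
  back <- read_image_png(png_path)
  expect_equal(dim(back), dim(co$maps[[1]]$pixels))
  expect_lt(max(abs(back - co$maps[[1]]$pixels)), 1 / 255)
  csv_path <- withr::local_tempfile(fileext = ".csv")
  write_subject_table(co$table, csv_path)
  back_tab <- read_subject_table(csv_path)
  expect_equal(back_tab$image_id, co$table$image_id)
  expect_equal(back_tab$age, co$table$age)
})

test_that("planted cohorts mark the signal region and honour a zero effect", {
  co <- generate_planted_cohort(5, 16, signal_fraction = 0.05,
                                effect_size = 2, seed = 3)
  expect_lte(mean(co$region), 0.0625)
  expect_gt(sum(co$region), 0)
  shift <- mean(vapply(co$ad, function(m) mean(m[co$region]), numeric(1))) -
    mean(vapply(co$nc, function(m) mean(m[co$region]), numeric(1)))
  expect_gt(shift, 1)  # planted shift of 2 sd, n = 5: well above 1
  null <- generate_planted_cohort(5, 16, effect_size = 0, seed = 3)
  expect_identical(null$nc, co$nc)
})
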