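test_that("trait definitions and modalities round-trip through CSV", {
  specs <- toy_specs()
  a <- data.frame(size = c("s", "m", NA),
                  colour = c("red", NA, "blue"),
                  mobility = c("low", "low", "high"),
                  row.names = c("spA", "spB", "spC"))
  tt <- trait_table(a, specs)
  dfile <- withr::local_tempfile(fileext = ".csv")
  mfile <- withr::local_tempfile(fileext = ".csv")
  write_trait_table(specs, tt, dfile, mfile)
  back <- read_trait_table(dfile, mfile)
  expect_equal(back$table$assignment, tt$assignment)
  expect_equal(names(back$specs), names(specs))
  expect_equal(back$specs$size$levels, specs$size$levels)
  expect_equal(back$specs$size$kind, "ordered")
})

test_that("the default trait set has 8 traits, 4 of them ordered", {
  specs <- default_trait_specs()
  expect_length(specs, 8L)
  kinds <- vapply(specs, `[[`, "", "kind")
  expect_equal(sum(kinds == "ordered"), 4L)
  expect_setequal(names(specs)[kinds == "ordered"],
                  c("maximum adult body size", "trophic mode",
                    "relative adult mobility", "external protection"))
  # read back from a definitions file written from the specs
  dfile <- withr::local_tempfile(fileext = ".csv")
  mfile <- withr::local_tempfile(fileext = ".csv")
  a <- data.frame(`maximum adult body size` = c("small (~1 mm)", "large (~100 mm)"),
                  check.names = FALSE, row.names = c("x", "y"))
  write_trait_table(specs, trait_table(a, specs["maximum adult body size"]),
                    dfile, mfile)
  expect_length(read_trait_table(dfile, mfile)$specs, 8L)
})

test_that("trait table validation names the offending species and trait", {
  specs <- toy_specs()
  a <- data.frame(size = c("s", "huge"), row.names = c("spA", "spB"))
  expect_error(trait_table(a, specs), "spB.*size.*huge")
  expect_error(trait_table(a[0, , drop = FALSE], specs), "no species")
  a2 <- data.frame(size = c("s", NA), colour = c("red", NA),
                   row.names = c("spA", "spB"))
  expect_error(trait_table(a2, specs), "no non-missing")
  mfile <- withr::local_tempfile(fileext = ".csv")
  dfile <- withr::local_tempfile(fileext = ".csv")
  writeLines("trait,type,modality\nsize,ordered,s\nsize,ordered,m", dfile)
  writeLines("species,trait,modality", mfile)
  expect_error(read_trait_table(dfile, mfile), "no species")
})

test_that("wide and long abundance dialects yield identical tables", {
  meta <- data.frame(sample_id = c("s1", "s2"),
                     surface_kind = "sandwich", epoch = "post_eruption",
                     time_months = c(9, 22), recovery_temp_C = c(2, 3),
                     deployment_months = c(6, 6))
  widef <- withr::local_tempfile(fileext = ".csv")
  longf <- withr::local_tempfile(fileext = ".csv")
  writeLines("sample,spA,spB\ns1,3,0\ns2,2,5", widef)
  writeLines(paste("sample,species,count", "s1,spA,3", "s1,spB,0",
                   "s2,spA,2", "s2,spB,5", sep = "\n"), longf)
  w <- read_abundance(widef, metadata = meta)
  l <- read_abundance(longf, metadata = meta)
  expect_identical(w$counts, l$counts)
  expect_identical(w$samples, l$samples)
  # metadata embedded in the long file works too
  embf <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(
    "sample,species,count,time_months,temperature,epoch,kind,deployment",
    "s1,spA,3,9,2,post_eruption,sandwich,6",
    "s1,spB,0,9,2,post_eruption,sandwich,6",
    "s2,spA,2,22,3,post_eruption,sandwich,6",
    "s2,spB,5,22,3,post_eruption,sandwich,6", sep = "\n"), embf)
  e <- read_abundance(embf)
  expect_identical(e$counts, w$counts)
  expect_equal(e$samples$recovery_temp_C, c(2, 3))
})

test_that("malformed abundance files are rejected", {
  meta <- data.frame(sample_id = "s1", surface_kind = "sandwich",
                     epoch = "post_eruption", time_months = 9,
                     recovery_temp_C = 2, deployment_months = 6)
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("sample,species,count\ns1,spA,-1", f)
  expect_error(read_abundance(f, metadata = meta), "non-negative")
  writeLines("sample,species,count\ns1,spA,1.5", f)
  expect_error(read_abundance(f, metadata = meta), "non-negative")
  writeLines("sample,species,count\ns1,spA,1\ns1,spA,2", f)
  expect_error(read_abundance(f, metadata = meta), "duplicate")
})

test_that("temperature filtering is inclusive, order-preserving, idempotent", {
  ab <- toy_abundance()
  f <- filter_samples(ab, 1.9, 6.5)
  expect_equal(nrow(f$counts), 5L)  # 6.5 and 1.9 boundaries retained
  f2 <- filter_samples(ab, 2.0, 5.0)
  expect_equal(f2$samples$sample_id, c("a1", "a2", "b1"))
  expect_identical(filter_samples(f2, 2.0, 5.0), f2)
  expect_warning(filter_samples(ab, 10, 11), "no samples")
  expect_error(filter_samples(ab, 5, 2), "temp_min")
})

test_that("species retention drops taxa without trait data and reports them", {
  ab <- toy_abundance()
  specs <- toy_specs()
  a <- data.frame(size = c("s", "m"), row.names = c("sp1", "sp3"))
  tt <- trait_table(a, specs["size"])
  expect_message(out <- retain_species(ab, tt), "sp2")
  expect_equal(out$taxa, c("sp1", "sp3"))
  expect_equal(attr(out, "dropped")$total_count, 12)
  # full coverage is the identity
  afull <- data.frame(size = c("s", "m", "l"),
                      row.names = c("sp1", "sp2", "sp3"))
  full <- retain_species(ab, trait_table(afull, specs["size"]))
  expect_identical(full$counts, ab$counts)
  # empty coverage warns
  anone <- data.frame(size = "s", row.names = "other")
  expect_warning(suppressMessages(none <- retain_species(
    ab, trait_table(anone, specs["size"]))), "no taxa")
  expect_equal(ncol(none$counts), 0L)
})

test_that("pooling sums surfaces by recovery date and conserves individuals", {
  ab <- toy_abundance()
  ps <- pool_by_time(ab)
  expect_equal(rownames(ps$counts), c("pre", "9", "22"))
  expect_equal(unname(ps$counts["9", ]), c(5, 5, 2))  # (3,0,2) + (2,5,0)
  expect_equal(colSums(ps$counts), colSums(ab$counts))
  expect_true(ps$is_pre[1] && !any(ps$is_pre[-1]))
  # one sample per time: pooling is the identity on counts
  one <- abundance_table(ab$counts[c(1, 3), ],
                         ab$samples[c(1, 3), ])
  ps1 <- pool_by_time(one)
  expect_equal(unname(ps1$counts), unname(ab$counts[c(1, 3), ]))
})

test_that("pooled column totals equal input column totals on a larger fixture", {
  cfg <- synth_config(n_species = 10, n_guilds = 3, seed = 11)
  ab <- make_abundances(cfg)
  ps <- pool_by_time(ab)
  expect_equal(colSums(ps$counts), colSums(ab$counts))
  expect_equal(sum(ps$counts), sum(ab$counts))
})

test_that("modality abundance matches hand computation and conserves totals", {
  specs <- toy_specs()
  # 5 species, one with a missing assignment for 'size'
  a <- data.frame(size = c("s", "m", "m", NA, "xl"),
                  colour = c("red", "red", "green", "blue", "blue"),
                  row.names = paste0("sp", 1:5))
  tt <- trait_table(a, specs[c("size", "colour")])
  counts <- matrix(c(10, 1, 2, 4, 7), 1,
                   dimnames = list("t1", paste0("sp", 1:5)))
  samples <- data.frame(sample_id = "t1", surface_kind = "sandwich",
                        epoch = "post_eruption", time_months = 9,
                        recovery_temp_C = 2, deployment_months = 6)
  ps <- pool_by_time(abundance_table(counts, samples))
  ma <- modality_abundance(ps, tt, specs$size)
  # by hand: s = sp1 = 10; m = sp2 + sp3 = 3; l = 0; xl = sp5 = 7; sp4 skipped
  expect_equal(unname(ma["9", ]), c(10, 3, 0, 7))
  expect_equal(sum(ma), sum(counts) - 4)  # species missing the trait excluded
  mc <- modality_abundance(ps, tt, specs$colour)
  expect_equal(unname(mc["9", ]), c(11, 2, 11))
  expect_equal(sum(mc), sum(counts))
  # one species per modality with unit counts -> identity rows
  a2 <- data.frame(colour = c("red", "green", "blue"),
                   row.names = paste0("u", 1:3))
  tt2 <- trait_table(a2, specs["colour"])
  counts2 <- matrix(1, 1, 3, dimnames = list("t1", paste0("u", 1:3)))
  ps2 <- pool_by_time(abundance_table(counts2, samples))
  expect_equal(unname(modality_abundance(ps2, tt2, specs$colour)["9", ]),
               c(1, 1, 1))
})
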