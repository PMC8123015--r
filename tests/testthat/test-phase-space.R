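# Phase-space container: construction invariants, lossless IO, spectra.

test_that("binary container round-trips records bit-exactly", {
  ps <- phase_space(random_records(1000), n_primaries = 500,
                    stage = "test", source = "rng", seed = 1L)
  f <- tempfile(fileext = ".phsp")
  write_phase_space(ps, f)
  ps2 <- read_phase_space(f)
  expect_identical(ps2$records, ps$records)
  expect_identical(ps2$header$n_primaries, 500)
  expect_identical(ps2$header$geometry_hash, ps$header$geometry_hash)
  unlink(f)
})

test_that("empty record list round-trips with the history count preserved", {
  ps <- phase_space(data.frame(), n_primaries = 42)
  f <- tempfile()
  write_phase_space(ps, f)
  ps2 <- read_phase_space(f)
  expect_equal(nrow(ps2$records), 0)
  expect_identical(ps2$header$n_primaries, 42)
  unlink(f)
})

test_that("invalid records are rejected on construction and on read", {
  r <- random_records(3)
  r$ux[1] <- 0.9; r$uy[1] <- 0; r$uz[1] <- 0
  expect_error(phase_space(r, 3), "unit vectors")
  r <- random_records(3); r$energy_eV[2] <- -1
  expect_error(phase_space(r, 3), "positive")
  r <- random_records(3); r$weight[3] <- 0
  expect_error(phase_space(r, 3), "positive")
  expect_error(phase_space(random_records(2), 0), "n_primaries")
  # a file holding a non-unit direction must be rejected when read back
  ps <- phase_space(random_records(5), 5)
  f <- tempfile()
  write_phase_space(ps, f)
  bytes <- readBin(f, "raw", file.size(f))
  # locate the first record's ux field (header ends at 'records:\n')
  hdr_end <- grepRaw("records:\n", bytes, fixed = TRUE) + 8
  ux_off <- hdr_end + 1 + 4 * 8
  bytes[(ux_off + 1):(ux_off + 8)] <- writeBin(2.0, raw(), size = 8,
                                               endian = "little")
  writeBin(bytes, f)
  expect_error(read_phase_space(f), "unit vectors")
  unlink(f)
})

test_that("truncated record sections raise a parse error with an offset", {
  ps <- phase_space(random_records(10), 10)
  f <- tempfile()
  write_phase_space(ps, f)
  bytes <- readBin(f, "raw", file.size(f))
  writeBin(bytes[1:(length(bytes) - 20)], f)
  expect_error(read_phase_space(f), "truncated record section at byte")
  unlink(f)
})

test_that("CSV twin reproduces every field", {
  ps <- phase_space(random_records(200), 100, stage = "csv", seed = 3L)
  f <- tempfile(fileext = ".csv")
  write_phase_space_csv(ps, f)
  ps2 <- read_phase_space_csv(f)
  expect_equal(ps2$records, ps$records, tolerance = 1e-15)
  expect_identical(ps2$header$n_primaries, 100)
  unlink(f)
})

test_that("spectra: delta line, weight linearity, weight closure", {
  ps <- make_pencil_beam(662e3, 50)
  br <- c(1e3, 1e5, 6e5, 7e5)
  sp <- summarize_spectrum(ps, "photon", br)
  expect_equal(sp$count_per_primary, c(0, 0, 1))
  # all weighted counts sum to the total record weight of the kind
  ps2 <- phase_space(random_records(400), 100)
  br2 <- seq(100, 7e5, length.out = 40)
  sp2 <- summarize_spectrum(ps2, "electron", br2)
  el <- ps2$records[ps2$records$kind == "electron", ]
  inside <- el$energy_eV >= br2[1] & el$energy_eV <= br2[length(br2)]
  expect_equal(sum(sp2$count_per_primary) * 100, sum(el$weight[inside]))
  # doubling the weights doubles every bin
  r3 <- ps2$records; r3$weight <- 2 * r3$weight
  sp3 <- summarize_spectrum(phase_space(r3, 100), "electron", br2)
  expect_equal(sp3$count_per_primary, 2 * sp2$count_per_primary)
  # no records of the kind: empty histogram with a warning
  expect_warning(sp4 <- summarize_spectrum(make_pencil_beam(1e3, 2),
                                           "electron", br),
                 "no records")
  expect_true(all(sp4$count_per_primary == 0))
  expect_error(summarize_spectrum(ps, "photon", c(1, 1, 2)),
               "strictly increasing")
})
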