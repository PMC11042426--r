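# MGF and feature-table I/O, run configuration.

mgf_text <- function(...) paste(c(...), collapse = "\n")

test_that("read_mgf maps block fields and sorts peaks", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(mgf_text(
    "BEGIN IONS", "TITLE=scan1", "PEPMASS=792.3 123456",
    "CHARGE=2+", "RTINSECONDS=900",
    "204.0867 100", "366.1395 50", "224.1118 30", "END IONS", "",
    "BEGIN IONS", "PEPMASS=512.2", "RTINSECONDS=301.5",
    "163.0601 10", "END IONS"), path)
  sp <- read_mgf(path, sample = "t")
  expect_length(sp, 2L)
  expect_equal(sp[[1]]$id, "scan1")
  expect_equal(sp[[1]]$precursor_mz, 792.3)
  expect_equal(sp[[1]]$charge, 2L)
  expect_equal(sp[[1]]$rt, 900)
  # unsorted input peaks come back ascending with content preserved
  expect_equal(sp[[1]]$mz, c(204.0867, 224.1118, 366.1395))
  expect_equal(sp[[1]]$intensity, c(100, 30, 50))
  # missing CHARGE -> unknown
  expect_true(is.na(sp[[2]]$charge))
})

test_that("read_mgf rejects malformed blocks and warns on empty files", {
  bad <- withr::local_tempfile(fileext = ".mgf")
  writeLines(mgf_text("BEGIN IONS", "RTINSECONDS=10", "END IONS"), bad)
  expect_error(read_mgf(bad), "PEPMASS")
  nort <- withr::local_tempfile(fileext = ".mgf")
  writeLines(mgf_text("BEGIN IONS", "PEPMASS=500", "END IONS"), nort)
  expect_error(read_mgf(nort), "RTINSECONDS")
  empty <- withr::local_tempfile(fileext = ".mgf")
  writeLines("", empty)
  expect_warning(out <- read_mgf(empty), "no spectra")
  expect_length(out, 0L)
})

test_that("MGF write/read round-trips fields and peaks", {
  sps <- list(
    make_spec(c(204.0867, 224.1118), c(100, 30), id = "a",
              precursor_mz = 1186.4355, charge = 2L, rt = 900.25),
    make_spec(c(163.0601), c(5), id = "b", precursor_mz = 700.1,
              charge = NA_integer_, rt = 12.5))
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sps, path)
  back <- read_mgf(path, sample = "test")
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_equal(back[[i]]$id, sps[[i]]$id)
    expect_equal(back[[i]]$precursor_mz, sps[[i]]$precursor_mz,
                 tolerance = 1e-6)
    expect_equal(back[[i]]$rt, sps[[i]]$rt, tolerance = 1e-4)
    expect_equal(back[[i]]$mz, sps[[i]]$mz, tolerance = 1e-6)
    expect_equal(back[[i]]$intensity, sps[[i]]$intensity, tolerance = 1e-6)
  }
  # unknown charge stays unknown (no CHARGE line written)
  expect_true(is.na(back[[2]]$charge))
  expect_false(any(grepl("^CHARGE", readLines(path)[
    grep("TITLE=b", readLines(path)):length(readLines(path))])))
  # write(read(write(x))) is stable
  path2 <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(back, path2)
  expect_identical(readLines(path), readLines(path2))
  # empty list -> valid empty file
  path3 <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(list(), path3)
  expect_warning(expect_length(read_mgf(path3), 0L))
})

test_that("written MGF agrees with an independent parser", {
  # pyteomics as external oracle for the dialect
  sp <- make_spec(c(204.0867, 224.1118, 366.1395), c(100, 30, 50),
                  id = "oracle1", precursor_mz = 1186.4355, charge = 2L,
                  rt = 901.5)
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(list(sp), path)
  out <- system2("python", c("-c", shQuote(paste0(
    "from pyteomics import mgf\n",
    "s = next(mgf.read('", path, "'))\n",
    "p = s['params']\n",
    "print(p['title'], p['pepmass'][0], int(p['charge'][0]),",
    " p['rtinseconds'], len(s['m/z array']), round(s['m/z array'][1], 4))"
  ))), stdout = TRUE)
  fields <- strsplit(out[length(out)], " ")[[1]]
  expect_equal(fields[1], "oracle1")
  expect_equal(as.numeric(fields[2]), 1186.4355, tolerance = 1e-5)
  expect_equal(as.integer(fields[3]), 2L)
  expect_equal(as.numeric(fields[4]), 901.5, tolerance = 1e-3)
  expect_equal(as.integer(fields[5]), 3L)
  expect_equal(as.numeric(fields[6]), 224.1118, tolerance = 1e-4)
})

test_that("feature tables convert neutral masses to [M+H]+ and drop zeros", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("rt_seconds,neutral_monoisotopic_mass,charge,abundance",
               "1200,2370.8566,2,1e7",
               "1300,1500.5,1,0",
               "900,1236.4492,1,5e6"), path)
  expect_message(f <- read_features(path, sample = "s"), "dropped 1")
  expect_equal(nrow(f), 2L)
  expect_equal(f$mass[1], 2370.8566 + 1.00727646688, tolerance = 1e-6)
  # header-only file -> empty table
  h <- withr::local_tempfile(fileext = ".csv")
  writeLines("rt_seconds,neutral_monoisotopic_mass,charge,abundance", h)
  expect_equal(nrow(read_features(h)), 0L)
  # missing column -> informative error
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("rt_seconds,charge,abundance", "1,1,1"), bad)
  expect_error(read_features(bad), "mass")
  # DeCon2-style headers are accepted
  d2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("scan_time,monoisotopic_mw,charge,abundance",
               "1000,1236.4492,2,2e6"), d2)
  expect_equal(read_features(d2)$mass, 1237.4565, tolerance = 1e-4)
})

test_that("feature tables round-trip through write/read", {
  f <- data.frame(mass = c(1237.4565, 2371.8638), rt = c(840, 1290),
                  intensity = c(2e7, 1e7), sample = "x")
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(f, path)
  back <- read_features(path, sample = "x")
  expect_equal(back$mass, f$mass, tolerance = 1e-9)
  expect_equal(back$intensity, f$intensity)
})

test_that("run configuration validates and loads from YAML", {
  cfg <- run_config()
  expect_equal(cfg$bin_low, 1000)
  expect_equal(cfg$bin_high, 5000)
  expect_equal(cfg$intensity_threshold, 5e6)
  expect_equal(cfg$snog_cutoff, 0.03)
  expect_error(run_config(bin_low = 10, bin_high = 5), "bin_low")
  expect_error(run_config(snog_cutoff = 2), "snog_cutoff")
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("bin_low: 1200", "snog_cutoff: 0.05"), path)
  cfg2 <- read_run_config(path)
  expect_equal(cfg2$bin_low, 1200)
  expect_equal(cfg2$snog_cutoff, 0.05)
  expect_equal(cfg2$rt_bin, 10)
  bad <- withr::local_tempfile(fileext = ".yml")
  writeLines("bogus_key: 1", bad)
  expect_error(read_run_config(bad), "bogus_key")
})
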