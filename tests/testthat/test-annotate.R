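sig <- function(pos, chrom = 1L, score = 1, method = "fst",
                population = "both") {
  tibble::tibble(chrom = chrom, pos_bp = pos,
                 snp_id = paste0("s", seq_along(pos)), score = score,
                 method = method, population = population)
}

test_that("windows are centred, clipped, and merged with the peak retained", {
  w <- make_windows(sig(300000))
  expect_equal(c(w$start_bp, w$end_bp), c(50000, 550000))

  wc <- make_windows(sig(100000))
  expect_equal(c(wc$start_bp, wc$end_bp), c(1, 350000))

  wl <- make_windows(sig(900000), chrom_lengths = c("1" = 1000000))
  expect_equal(wl$end_bp, 1000000)

  wm <- make_windows(sig(c(300000, 400000), score = c(0.2, 0.5)))
  expect_equal(nrow(wm), 1L)
  expect_equal(c(wm$start_bp, wm$end_bp), c(50000, 650000))
  expect_equal(wm$merged_from, 2L)
  expect_equal(wm$peak_snp_id, "s2")  # larger |score| wins the peak

  expect_equal(nrow(make_windows(sig(numeric(0)))), 0L)
})

test_that("windows from different methods or populations never merge", {
  s <- dplyr::bind_rows(sig(300000, method = "fst"),
                        sig(400000, method = "ihs", population = "dairy"))
  w <- make_windows(s)
  expect_equal(nrow(w), 2L)
  expect_setequal(w$method, c("fst", "ihs"))
})

test_that("interval overlap is 1-based inclusive with a 1-bp minimum", {
  # the worked gene example: significant SNP inside the gene body
  win <- make_windows(sig(25933132, chrom = 16L, method = "ihs",
                          population = "dairy"))
  genes <- tibble::tibble(chrom = 16L, start_bp = 25895748, end_bp = 25936856,
                          name = "DUSP10", category = "gene")
  hit <- overlap_intervals(win, genes)
  expect_equal(hit$name, "DUSP10")
  expect_equal(hit$methods, "ihs")

  # interval ending exactly at the window start still overlaps by 1 bp
  win2 <- make_windows(sig(500000))
  edge <- tibble::tibble(chrom = 1L, start_bp = 200000,
                         end_bp = win2$start_bp, name = "EDGE",
                         category = "gene")
  expect_equal(overlap_intervals(win2, edge)$name, "EDGE")
  # one bp short of the window start: no overlap
  miss <- dplyr::mutate(edge, end_bp = win2$start_bp - 1)
  expect_equal(nrow(suppressWarnings(overlap_intervals(win2, miss))), 0L)

  far <- tibble::tibble(chrom = 9L, start_bp = 1, end_bp = 100,
                        name = "FAR", category = "gene")
  expect_warning(none <- overlap_intervals(win2, far), "skipped")
  expect_equal(nrow(none), 0L)
})

test_that("consensus genes union supporting methods and filter by support", {
  h_fst <- tibble::tibble(name = c("CTNNA2", "NSG1"), category = "gene",
                          chrom = c(2L, 6L), start_bp = c(100, 200),
                          end_bp = c(1000, 2000), n_windows = 1L,
                          methods = "fst", populations = "both")
  h_ihs <- tibble::tibble(name = "CTNNA2", category = "gene", chrom = 2L,
                          start_bp = 100, end_bp = 1000, n_windows = 1L,
                          methods = "ihs", populations = "dairy")
  cons <- consensus_genes(list(h_fst, h_ihs))
  both <- cons[cons$name == "CTNNA2", ]
  expect_equal(both$n_methods, 2L)
  expect_equal(both$methods, "fst,ihs")
  expect_equal(cons$n_methods[cons$name == "NSG1"], 1L)
  expect_equal(consensus_genes(list(h_fst, h_ihs), min_methods = 2)$name,
               "CTNNA2")

  # disjoint lists give singleton support everywhere
  h_b <- dplyr::mutate(h_fst, name = c("A1", "A2"))
  disj <- consensus_genes(list(h_b, h_ihs))
  expect_true(all(disj$n_methods == 1L))
})
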