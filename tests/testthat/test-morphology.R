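test_that("toy neuron morphometry matches construction", {
  m <- toy_neuron()
  s <- summarize_morphology(m)
  expect_equal(s$len_total, 200)
  expect_equal(s$len_abd, 100)
  expect_equal(s$len_nabd_total, 100)
  expect_equal(s$axon_soma_distance, 30)
  expect_equal(s$axon_start_length, 10)
  expect_equal(s$ais_soma_distance, 40)
  expect_equal(s$ais_length, 25)
  expect_false(s$has_somatic_axon)
  ## the collinear split at the axon origin does not create a segment
  expect_equal(s$n_segments_total, 2L)
  expect_equal(s$n_segments_abd, 1L)
  expect_identical(identify_abd(m), 2L)
})

test_that("somatic-axon neurons have undefined ABD metrics", {
  m <- toy_somatic_neuron()
  s <- summarize_morphology(m)
  expect_true(s$has_somatic_axon)
  expect_true(is.na(s$len_abd))
  expect_true(is.na(s$n_segments_abd))
  expect_true(is.na(count_segments(m, "abd")))
  expect_equal(s$axon_soma_distance, 0)
  expect_equal(s$ais_soma_distance, s$axon_start_length)
  expect_equal(s$n_segments_nabd, 2L)
  expect_true(is.na(identify_abd(m)))
})

test_that("segment counts match the brute-force oracle on random trees", {
  set.seed(11)
  for (k in c(0L, 1L, 3L, 7L, 12L, 20L)) {
    m <- random_tree_neuron(k)
    expect_identical(count_segments(m, "all"), 2L * k + 1L)
    expect_identical(count_segments(m, "all"),
                     as.integer(brute_force_segments(m)))
  }
})

test_that("summary is invariant to collinear section subdivision", {
  m <- toy_neuron()
  ## split the nABD (section 4) into two collinear halves
  s <- m$sections
  i <- which(s$id == 4)
  s$length[i] <- 40
  s <- rbind(s, data.frame(id = 8L, label = "dendrite", parent = 4L,
                           length = 60, diam_prox = 2, diam_dist = 2))
  m2 <- neuron_morphology(s, soma_volume = m$soma_volume)
  expect_equal(as.data.frame(summarize_morphology(m2)),
               as.data.frame(summarize_morphology(m)))
})

test_that("additive identities hold (length, segments, AIS distance)", {
  set.seed(21)
  pop <- sample_population(default_stage_params("P14"), 25)
  tab <- summarize_population(pop)
  abd_len <- ifelse(is.na(tab$len_abd), 0, tab$len_abd)
  abd_seg <- ifelse(is.na(tab$n_segments_abd), 0L, tab$n_segments_abd)
  expect_equal(tab$len_total, abd_len + tab$len_nabd_total)
  expect_equal(tab$n_segments_total, abd_seg + tab$n_segments_nabd)
  expect_equal(tab$ais_soma_distance,
               tab$axon_soma_distance + tab$axon_start_length)
  expect_equal(tab$len_nabd_avg, tab$len_nabd_total / tab$n_primary_nabd)
  ## the published mature-stage means satisfy the same identity
  expect_equal(33.25 + 21.61, 54.85, tolerance = 0.01)
})

test_that("equivalent cylinder has length = diameter and conserves volume", {
  ec <- equivalent_cylinder(pi / 4)
  expect_equal(ec$diameter, 1)
  expect_equal(ec$length, 1)
  expect_equal(equivalent_cylinder(2489)$diameter, 14.69, tolerance = 1e-3)
  for (v in c(0.1, 12, 1103, 2845)) {
    ec <- equivalent_cylinder(v)
    expect_equal(pi * ec$diameter^2 / 4 * ec$length, v, tolerance = 1e-9)
  }
  expect_error(equivalent_cylinder(-1), "positive")
})

test_that("tapering interpolates to the terminal diameter", {
  ## one primary stem (30 um) then a single 100 um daughter chain split in
  ## two sections: taper from stem diameter 2.0 to 0.5 at the tip
  secs <- data.frame(
    id = 1:7,
    label = c("soma", "dendrite", "dendrite", "dendrite", "axon_start",
              "ais", "axon"),
    parent = c(NA, 1, 2, 2, 1, 5, 6),
    length = c(10, 30, 50, 50, 10, 25, 50),
    diam_prox = c(10, 2, 2, 2, 1, 1, 1),
    diam_dist = c(10, 2, 2, 2, 1, 1, 1))
  ## two daughters -> section 2 is the full stem, 3 and 4 taper over 50 um
  m <- neuron_morphology(secs, soma_volume = 1000)
  mt <- apply_taper(m, terminal_diam = 0.5, axon_diam = 0.7)
  s <- mt$sections
  expect_equal(s$diam_prox[s$id == 2], 2)
  expect_equal(s$diam_dist[s$id == 2], 2)
  ## daughters run the full remaining path: tip exactly 0.5
  expect_equal(s$diam_dist[s$id == 3], 0.5)
  expect_equal(s$diam_dist[s$id == 4], 0.5)
  ## midpoint of the taper path: (2 + 0.5) / 2
  expect_equal(s$diam_prox[s$id == 3], 2)
  mid <- (s$diam_prox[s$id == 3] + s$diam_dist[s$id == 3]) / 2
  expect_equal(mid, 1.25)
  ## axonal sections forced to the constant axonal diameter
  expect_true(all(s$diam_prox[s$label %in% c("axon_start", "ais", "axon")]
                  == 0.7))
  ## an unbranched dendrite is all stem: untouched
  m2 <- apply_taper(toy_somatic_neuron())
  expect_equal(m2$sections$diam_prox[m2$sections$label == "dendrite"],
               c(2, 2))
  expect_error(apply_taper(m, terminal_diam = 0), "positive")
})

test_that("SWC round trip preserves the morphometric summary", {
  set.seed(31)
  m <- sample_neuron(default_stage_params("P21"))
  path <- file.path(tempdir(), "rt.swc")
  save_morphology(m, path)
  m2 <- load_morphology(path)
  s1 <- as.data.frame(summarize_morphology(m))
  s2 <- as.data.frame(summarize_morphology(m2))
  num <- vapply(s1, is.numeric, logical(1))
  expect_equal(unlist(s2[num]), unlist(s1[num]), tolerance = 1e-6)
  unlink(c(path, paste0(path, ".json")))
})

test_that("SWC loader reports malformed and disconnected inputs", {
  p <- file.path(tempdir(), "bad.swc")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 10 0 0 1"), p)  # 6 columns
  expect_error(load_morphology(p), "line 2")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 10 0 0 1 99"), p)  # missing parent
  expect_error(load_morphology(p), "missing parent")
  writeLines(c("# comment", "1 1 0 0 0 5 -1", "2 3 10 0 0 1 1"), p)
  m <- load_morphology(p)   # minimal soma + one dendrite, no axon path
  expect_equal(sum(m$sections$label == "dendrite"), 1L)
  expect_equal(m$sections$length[m$sections$label == "dendrite"], 10)
  unlink(p)
  expect_error(load_morphology("/nonexistent.swc"), "not found")
})

test_that("a three-point SWC yields one dendrite of the stated length", {
  p <- file.path(tempdir(), "three.swc")
  writeLines(c("1 1 0 0 0 6 -1", "2 3 50 0 0 1 1", "3 3 150 0 0 1 2"), p)
  m <- load_morphology(p)
  expect_equal(sum(m$sections$length[m$sections$label == "dendrite"]), 150)
  expect_equal(count_segments(m, "all"), 1L)
  unlink(p)
})
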