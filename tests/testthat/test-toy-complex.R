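# The synthetic tetramer + wrapped-DNA reference complex.

test_that("the tetramer obeys D2 symmetry and steric bounds", {
  cx <- make_toy_tetramer(seed = 1)
  xyz <- as.matrix(cx$protein[, c("x", "y", "z")])
  n_res <- nrow(xyz) / 4
  dmat <- function(s) {
    as.matrix(stats::dist(xyz[cx$protein$chain == LETTERS[s], ]))
  }
  ref <- dmat(1)
  for (s in 2:4) expect_lt(max(abs(dmat(s) - ref)), 1e-6)
  # no clashes anywhere in the complex
  all_xyz <- rbind(xyz, cx$dna$S, cx$dna$B, cx$dna$P)
  expect_gte(min(stats::dist(all_xyz)), 3.5)
})

test_that("the wrapped reference forms interfaces on every subunit", {
  cx <- make_toy_tetramer(seed = 1)
  params <- sim_params()
  prot <- build_protein_topology(cx$protein, params)
  dna <- build_ssdna_topology(cx$sequence, coords = cx$dna, params = params)
  topo <- merge_topologies(prot, dna, params)
  expect_gt(nrow(topo$interface), 0L)
  per_sub <- table(topo$subunit[topo$interface$i])
  expect_equal(length(per_sub), 4L)
  expect_true(all(per_sub >= 5L))
})

test_that("generation is reproducible and respects the residue floor", {
  c1 <- make_toy_tetramer(seed = 8)
  c2 <- make_toy_tetramer(seed = 8)
  expect_identical(c1$protein, c2$protein)
  expect_identical(c1$dna, c2$dna)
  expect_identical(c1$overlays, c2$overlays)
  c3 <- make_toy_tetramer(seed = 9)
  expect_false(identical(c3$protein, c1$protein))
  expect_error(make_toy_tetramer(n_res_per_subunit = 10), "n_res_per_subunit")
})

test_that("overlays cover the charged residues with the designed totals", {
  cx <- make_toy_tetramer(seed = 1)
  ov <- cx$overlays
  expect_setequal(unique(ov$state), c("unbridged", "bridged"))
  # 8 groove + 4 rim residues per subunit and state
  expect_equal(nrow(ov), 2 * 4 * 12)
  net <- tapply(ov$charge_e, ov$state, sum)
  expect_gt(net[["bridged"]], net[["unbridged"]])
  # the bridged groove is uniformly positive, the unbridged groove dispersed
  groove_key <- paste(cx$groove_residues$subunit, cx$groove_residues$residue_index)
  ov_key <- paste(ov$subunit, ov$residue_index)
  gb <- ov$charge_e[ov$state == "bridged" & ov_key %in% groove_key]
  gu <- ov$charge_e[ov$state == "unbridged" & ov_key %in% groove_key]
  expect_true(all(gb > 0))
  expect_equal(sum(gu), 0, tolerance = 1e-12)
})

test_that("PDB round trip preserves the complex geometry", {
  cx <- make_toy_tetramer(seed = 1)
  tf <- tempfile(fileext = ".pdb")
  write_complex_pdb(cx, tf)
  back <- read_complex_pdb(tf)
  expect_equal(as.matrix(back$protein[, c("x", "y", "z")]),
               as.matrix(cx$protein[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(back$dna$S, cx$dna$S, tolerance = 1e-3)
  expect_equal(back$dna$B, cx$dna$B, tolerance = 1e-3)
  expect_equal(back$sequence, cx$sequence)
  unlink(tf)
})
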