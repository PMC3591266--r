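# Window scanning, peaks, spots, within-protein permutation and motifs.

test_that("overlapping scan produces the documented starts and densities", {
  seqs <- c(W1 = seq_with(40, at = c(12, 14), residue = c("K", "S")))
  sites <- rbind(site_row("W1", 12, "Ac", seqs), site_row("W1", 12, "Ub", seqs),
                 site_row("W1", 14, "pST", seqs))
  ds <- new_ptm_dataset(sites, seqs)
  w <- scan_windows(ds, "W1")
  expect_equal(w$start, c(1L, 11L, 21L))
  # dual-modified lysine counts twice: window 1-20 holds 3 records
  expect_equal(w$n_mods[1], 3L)
  expect_equal(w$ptm_density[1], 0.15)
  expect_equal(w$n_types[1], 3L)
  # unmodified protein scans to all-zero densities
  dsz <- new_ptm_dataset(sites[0, ], seqs)
  expect_true(all(scan_windows(dsz, "W1")$ptm_density == 0))
  # shorter than one window: empty result
  seqs2 <- c(S1 = seq_with(15))
  short <- scan_windows(new_ptm_dataset(sites[0, ], seqs2), "S1")
  expect_equal(nrow(short), 0L)
})

test_that("window statistics equal a per-position brute-force recount", {
  b <- small_bundle(seed = 3)
  ds <- b$dataset
  for (p in utils::head(unique(ds$sites$protein_id), 10)) {
    w <- scan_windows(ds, p)
    s <- ds$sites[ds$sites$protein_id == p, ]
    ch <- strsplit(ds$sequences[[p]], "")[[1]]
    for (j in seq_len(nrow(w))) {
      span <- w$start[j]:w$end[j]
      expect_equal(w$n_mods[j], sum(s$position %in% span))
      expect_equal(w$styk_density[j], mean(ch[span] %in% c("S", "T", "Y", "K")))
      expect_equal(w$n_types[j], length(unique(s$ptm_type[s$position %in% span])))
    }
  }
})

test_that("local peaks are non-overlapping local maxima", {
  # density profile (0, 3, 3, 0)/20 over starts 1, 11, 21, 31: one peak,
  # the leftmost of the plateau pair
  seqs <- c(P1 = seq_with(50, at = c(25, 26, 27), residue = c("S", "S", "S")))
  sites <- site_row("P1", c(25L, 26L, 27L), rep("pST", 3), seqs)
  ds <- new_ptm_dataset(sites, seqs)
  pk <- local_peaks(scan_windows(ds, "P1"))
  expect_equal(pk$start, 11L)

  # flat positive profile: leftmost-first greedy keeps every other window
  seqs2 <- c(P2 = paste(rep("SAAAAAAAAA", 8), collapse = ""))
  pos <- seq(1L, 71L, by = 10L)
  ds2 <- new_ptm_dataset(site_row("P2", pos, rep("pST", length(pos)), seqs2), seqs2)
  w2 <- scan_windows(ds2, "P2")
  expect_true(all(w2$n_mods == 2L))
  pk2 <- local_peaks(w2)
  expect_equal(pk2$start, c(1L, 21L, 41L, 61L))

  # all-zero profile: no peaks
  dsz <- new_ptm_dataset(sites[0, ], seqs)
  expect_equal(nrow(local_peaks(scan_windows(dsz, "P1"))), 0L)

  # chosen peaks never overlap and dominate their scan neighbours
  b <- small_bundle(seed = 13)
  for (p in utils::head(unique(b$dataset$sites$protein_id), 8)) {
    w <- scan_windows(b$dataset, p)
    pk <- local_peaks(w)
    if (nrow(pk) > 1L)
      expect_true(all(pk$start[-1L] > pk$end[-nrow(pk)]))
    for (j in seq_len(nrow(pk))) {
      i <- match(pk$start[j], w$start)
      if (i > 1L) expect_gte(pk$ptm_density[j], w$ptm_density[i - 1L])
      if (i < nrow(w)) expect_gte(pk$ptm_density[j], w$ptm_density[i + 1L])
    }
  }
})

test_that("minimum site counts and state counts follow the density threshold", {
  expect_equal(min_sites_exceeding(20, 0.3), 7L)
  expect_equal(min_sites_exceeding(20, 0.05), 2L)  # 1/20 = 0.05 does not exceed
  # enumeration oracle for width 10
  oracle <- min(which(sapply(1:10, function(k) k / 10 > 0.3)))
  expect_equal(min_sites_exceeding(10, 0.3), oracle)
  expect_equal(oracle, 4L)
  expect_equal(modification_states(7), 128)
  expect_equal(modification_states(0), 1)
  expect_equal(modification_states(10), 1024)
})

test_that("spot calling merges overlapping/abutting dense windows", {
  # 7 pS in one aligned window: one single-classified spot of width 20
  seqs <- c(D1 = seq_with(60, at = 21:27, residue = rep("S", 7)))
  ds <- new_ptm_dataset(site_row("D1", 21:27, rep("pST", 7), seqs), seqs)
  sp <- call_spots(ds, "D1")
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$length, 30L)  # windows 11-30 and 21-40 both exceed theta
  expect_equal(sp$classification, "single")

  # sites spread so only the aligned window exceeds theta -> width 20 spot
  seqs2 <- c(D2 = seq_with(60, at = c(21, 24, 27, 30, 33, 36, 39),
                           residue = rep("S", 7)))
  ds2 <- new_ptm_dataset(site_row("D2", c(21L, 24L, 27L, 30L, 33L, 36L, 39L),
                                  rep("pST", 7), seqs2), seqs2)
  sp2 <- call_spots(ds2, "D2")
  expect_equal(nrow(sp2), 1L)
  expect_equal(c(sp2$start, sp2$end), c(21L, 40L))

  # two dense windows at starts 1 and 11 merge into one 1-30 spot
  seqs3 <- c(D3 = seq_with(40, at = 1:30, residue = rep("S", 30)))
  ds3 <- new_ptm_dataset(site_row("D3", c(1:7, 24:30), rep("pST", 14), seqs3), seqs3)
  w3 <- scan_windows(ds3, "D3")
  expect_true(all(w3$ptm_density[w3$start %in% c(1, 11)] > 0.3))
  sp3 <- call_spots(ds3, "D3")
  expect_equal(nrow(sp3), 1L)
  expect_gte(sp3$end - sp3$start + 1L, 30L)
})

test_that("within-protein permutation conserves positions and label multiset", {
  seqs <- c(T1 = seq_with(50, at = c(5, 30), residue = c("K", "S")))
  sites <- rbind(site_row("T1", 5, "Ac", seqs), site_row("T1", 30, "pST", seqs))
  p1 <- permute_types_within_protein(sites, seed = 2)
  expect_setequal(p1$position, c(5L, 30L))
  expect_setequal(p1$ptm_type, c("Ac", "pST"))
  # single-type sites: permutation is the identity in effect
  same <- rbind(site_row("T1", 5, "Ac", seqs), site_row("T1", 5, "Ub", seqs))
  same$ptm_type <- c("Ub", "Ub")
  expect_equal(sort(permute_types_within_protein(same, 3)$ptm_type),
               c("Ub", "Ub"))
  # fewer than two sites: identity
  one <- site_row("T1", 5, "Ac", seqs)
  expect_identical(permute_types_within_protein(one, 1), one)
})

test_that("label permutations are uniform over orderings", {
  seqs <- c(U1 = seq_with(40, at = c(5, 15, 25), residue = c("K", "S", "K")))
  sites <- rbind(site_row("U1", 5, "Ac", seqs),
                 site_row("U1", 15, "pST", seqs),
                 site_row("U1", 25, "Ub", seqs))
  seen <- character(1000)
  for (i in 1:1000)
    seen[i] <- paste(permute_types_within_protein(sites, i)$ptm_type,
                     collapse = "")
  freq <- table(seen) / 1000
  expect_equal(length(freq), 6L)
  expect_true(all(abs(freq - 1 / 6) <= 0.05))
})

test_that("compatibility-constrained permutation keeps labels chemically valid", {
  seqs <- c(V1 = seq_with(60, at = c(5, 15, 25, 35), residue = c("K", "K", "S", "Y")))
  sites <- rbind(site_row("V1", 5, "Ac", seqs), site_row("V1", 15, "Ub", seqs),
                 site_row("V1", 25, "pST", seqs), site_row("V1", 35, "pY", seqs))
  for (s in 1:20) {
    p <- permute_types_within_protein(sites, s, mode = "compatible")
    expect_true(all(mapply(function(r, t) r %in% PTM_COMPAT[[t]],
                           p$residue, p$ptm_type)))
  }
})

test_that("multi-PTM high-density counts match the label-permutation expectation", {
  # 3 pST clustered (dense peak) + 1 distant Ac: of the 4 equally likely
  # placements of the Ac label, 3 put it inside the peak window
  seqs <- c(X1 = seq_with(80, at = c(21, 24, 27, 60), residue = c("S", "S", "S", "K")))
  sites <- rbind(site_row("X1", c(21L, 24L, 27L), rep("pST", 3), seqs),
                 site_row("X1", 60, "Ac", seqs))
  ds <- new_ptm_dataset(sites, seqs)
  cfg <- scan_config(theta = 0.1)
  res <- multi_ptm_high_density_counts(ds, cfg, R = 400L, seed = 8)
  expect_equal(unname(res$observed["multi"]), 0L)
  expect_equal(unname(res$observed["single"]), 1L)
  # exact enumeration: label layouts are 4 choose 1 placements of Ac
  expect_equal(mean(res$null[, "multi"]), 3 / 4, tolerance = 0.1)

  # single-type proteome: multi count zero observed and under every permutation
  ds1 <- new_ptm_dataset(sites[sites$ptm_type == "pST", ], seqs)
  res1 <- multi_ptm_high_density_counts(ds1, cfg, R = 20L, seed = 1)
  expect_equal(unname(res1$observed["multi"]), 0L)
  expect_true(all(res1$null[, "multi"] == 0L))

  # reproducibility with a fixed seed
  res2 <- multi_ptm_high_density_counts(ds, cfg, R = 5L, seed = 8)
  res3 <- multi_ptm_high_density_counts(ds, cfg, R = 5L, seed = 8)
  expect_identical(res2, res3)

  # type-blind density profile is unchanged by permutation (exact)
  perm_sites <- permute_types_within_protein(ds$sites, 4)
  ds_perm <- new_ptm_dataset(perm_sites, seqs)
  expect_equal(scan_windows(ds_perm, "X1")$ptm_density,
               scan_windows(ds, "X1")$ptm_density)
})

test_that("PY-NLS matching follows the [RHK]X(2,5)PY core rule", {
  seqs <- c(N1 = paste0("AAA", "RAAPY", "AAAA", "RAPY", "AAAAA"))
  sites <- site_row("N1", 8, "pY", seqs)  # the Y of RAAPY
  ds <- new_ptm_dataset(sites, seqs)
  hits <- find_py_nls(ds, "N1")
  expect_equal(nrow(hits), 1L)  # RAPY (1-residue gap) must not match
  expect_equal(hits$match, "RAAPY")
  expect_equal(c(hits$start, hits$end), c(4L, 8L))
  expect_true(hits$py_on_motif_y)
  expect_equal(hits$n_mods_in_span, 1L)
  # no motif, no match
  expect_equal(nrow(find_py_nls(new_ptm_dataset(sites[0, ], c(N2 = seq_with(30))), "N2")), 0L)
})

test_that("hyperphospho-degron filter needs 4 pST, an SP site and a Ub site", {
  mk <- function(with_sp, n_pst = 4L, n_ub = 1L) {
    ch <- rep("A", 60)
    pst_pos <- c(21L, 24L, 27L, 30L, 33L)[seq_len(n_pst)]
    ch[pst_pos] <- "S"
    if (with_sp) ch[22L] <- "P"  # S at 21 followed by P
    ub_pos <- if (n_ub > 0L) 36L else integer(0)
    ch[ub_pos] <- "K"
    seqs <- c(G1 = paste(ch, collapse = ""))
    sites <- site_row("G1", pst_pos, rep("pST", n_pst), seqs)
    if (n_ub > 0L) sites <- rbind(sites, site_row("G1", ub_pos, "Ub", seqs))
    ds <- new_ptm_dataset(sites, seqs)
    list(ds = ds, spots = call_spots_all(ds, scan_config(theta = 0.1)))
  }
  yes <- mk(TRUE)
  expect_equal(nrow(find_hyperphospho_degrons(yes$spots, yes$ds)), 1L)
  no_sp <- mk(FALSE)
  expect_equal(nrow(find_hyperphospho_degrons(no_sp$spots, no_sp$ds)), 0L)
  few <- mk(TRUE, n_pst = 3L, n_ub = 2L)
  expect_equal(nrow(find_hyperphospho_degrons(few$spots, few$ds)), 0L)
})
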