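# Tiled windows and the domain/disorder/density/mutation classifications.

test_that("tiling discards trailing partial windows", {
  ds45 <- new_ptm_dataset(toy_dataset()$sites[0, ], c(T1 = seq_with(45)))
  w <- tile_windows(ds45, "T1")
  expect_equal(w$start, c(1L, 21L))
  expect_equal(w$end, c(20L, 40L))
  ds20 <- new_ptm_dataset(toy_dataset()$sites[0, ], c(T2 = seq_with(20)))
  expect_equal(nrow(tile_windows(ds20, "T2")), 1L)
  ds19 <- new_ptm_dataset(toy_dataset()$sites[0, ], c(T3 = seq_with(19)))
  expect_equal(nrow(tile_windows(ds19, "T3")), 0L)
})

test_that("domain overlap classes follow the 20/11-19/1-10/0 rule", {
  dom <- data.frame(protein_id = "X", name = "d", start = 21L, end = 60L)
  # windows fully inside (20), large overlap (14), small (5), external (0)
  starts <- c(31L, 15L, 56L, 81L)
  ends <- starts + 19L
  cls <- classify_domain_overlap(starts, ends, dom)
  expect_equal(cls, c("Int", "Lg", "Sm", "Ext"))
  # no domains at all: everything external
  expect_equal(classify_domain_overlap(starts, ends, dom[0, ]),
               rep("Ext", 4))
  # maximum single-domain overlap, not the union: window 11-30 overlaps
  # domain d by 10 and domain e by 5 (union 15 would be Lg; max stays Sm)
  two <- rbind(dom, data.frame(protein_id = "X", name = "e",
                               start = 1L, end = 15L))
  expect_equal(classify_domain_overlap(11L, 30L, two), "Sm")
})

test_that("disorder classes follow the 20/11-19/1-10/0 count rule", {
  track <- c(rep(1L, 20L), rep(0L, 10L), rep(1L, 12L), rep(0L, 8L))
  expect_equal(classify_disorder(1L, 20L, track), "High")
  expect_equal(classify_disorder(31L, 50L, track), "Med")  # 12 disordered
  expect_equal(classify_disorder(21L, 40L, track), "Low")  # 10 disordered
  expect_equal(classify_disorder(1L, 20L, rep(0L, 30L)), "none")
  expect_error(classify_disorder(41L, 60L, track[1:50]), "shorter")
})

test_that("density bins respect the boundary conventions", {
  cfg <- scan_config()
  expect_equal(classify_density_bin(0.4, cfg), "high")
  expect_equal(classify_density_bin(0.3, cfg), "medium")
  expect_equal(classify_density_bin(0.06, cfg), "medium")
  expect_equal(classify_density_bin(0.05, cfg), "low")   # 1 site per 20AA
  expect_equal(classify_density_bin(1 / 20, cfg), "low")
  expect_equal(classify_density_bin(0, cfg), "unmodified")
})

test_that("mutation flag respects kappa", {
  expect_true(mutated_window_flag(1L, 20L, c(5L, 15L), kappa = 2L))
  expect_false(mutated_window_flag(1L, 20L, 5L, kappa = 2L))
  expect_false(mutated_window_flag(1L, 20L, c(5L, 15L), kappa = 3L))
})

test_that("overlay classifications equal brute-force recounts and partition windows", {
  b <- generate_synthetic_bundle(synthetic_config(
    n_proteins = 25, mutations = list(rate = 0.05, domain_multiplier = 3,
                                      dense_multiplier = 1, theta = 0.3),
    seed = 19))
  w <- overlay_windows(b$dataset, b$domains, b$disorder, b$mutations)
  expect_gt(nrow(w), 0L)
  for (j in sample(seq_len(nrow(w)), 40L)) {
    p <- w$protein_id[j]; span <- w$start[j]:w$end[j]
    dom <- b$domains[b$domains$protein_id == p, ]
    ov <- 0L
    for (k in seq_len(nrow(dom)))
      ov <- max(ov, length(intersect(span, dom$start[k]:dom$end[k])))
    expect_equal(w$domain_class[j],
                 c("Ext", "Sm", "Lg", "Int")[findInterval(ov, c(0, 1, 11, 20))])
    expect_equal(w$n_mutations[j],
                 sum(b$mutations$position[b$mutations$protein_id == p] %in% span))
    dis <- sum(b$disorder[[p]][span])
    expect_equal(w$disorder_class[j],
                 c("none", "Low", "Med", "High")[findInterval(dis, c(0, 1, 11, 20))])
  }
  # each classification axis partitions the window set
  expect_equal(sum(table(w$domain_class)), nrow(w))
  expect_equal(sum(table(w$disorder_class)), nrow(w))
  expect_equal(sum(table(w$density_bin)), nrow(w))
})

test_that("mutation residue-match filter drops inconsistent records", {
  seqs <- c(P1 = seq_with(30, at = 10, residue = "K"))
  ds <- new_ptm_dataset(toy_dataset()$sites[0, ], seqs)
  f <- withr::local_tempfile(lines = c(
    "protein_id\tposition\tref_aa\talt_aa",
    "P1\t10\tK\tR",   # consistent
    "P1\t10\tS\tA",   # wrong reference residue
    "P1\t99\tA\tV"    # out of bounds
  ))
  mut <- parse_mutation_table(f, ds)
  expect_equal(nrow(mut), 1L)
  expect_match(attr(mut, "log"), "retained 1 of 3")
})

test_that("mutated fractions order as constructed", {
  seqs <- c(F1 = seq_with(100), F2 = seq_with(100))
  ds <- new_ptm_dataset(toy_dataset()$sites[0, ], seqs)
  dom <- data.frame(protein_id = c("F1", "F2"), name = "d",
                    start = 1L, end = 40L)
  # mutations only inside domains
  mut <- data.frame(protein_id = rep(c("F1", "F2"), each = 4L),
                    position = rep(c(5L, 6L, 25L, 26L), 2L),
                    ref_aa = "A", alt_aa = "V")
  w <- overlay_windows(ds, dom, list(), mut)
  tab <- mutated_fraction_table(w)
  int_f <- tab$fraction[tab$axis == "domain" & tab$category == "Int"]
  ext_f <- tab$fraction[tab$axis == "domain" & tab$category == "Ext"]
  expect_gt(int_f, ext_f)
  # no mutations anywhere: all defined fractions zero
  w0 <- overlay_windows(ds, dom, list(), mut[0, ])
  t0 <- mutated_fraction_table(w0)
  expect_true(all(t0$fraction[!is.na(t0$fraction)] == 0))
  # Ext windows: mutations implanted only in the dense window
  seqs2 <- c(H1 = seq_with(100, at = 41:47, residue = rep("S", 7)))
  sites2 <- site_row("H1", 41:47, rep("pST", 7), seqs2)
  ds2 <- new_ptm_dataset(sites2, seqs2)
  mut2 <- data.frame(protein_id = "H1", position = c(42L, 44L),
                     ref_aa = "S", alt_aa = "F")
  w2 <- overlay_windows(ds2, dom[0, ], list(), mut2)
  t2 <- mutated_fraction_table(w2)
  hi <- t2$fraction[t2$axis == "ext_density" & t2$category == "high"]
  un <- t2$fraction[t2$axis == "ext_density" & t2$category == "unmodified"]
  expect_equal(hi, 1)
  expect_equal(un, 0)
})
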