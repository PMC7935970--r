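# Register bookkeeping, motif placement, wheels, moments, masses.

test_that("register assignment follows the offset convention and is periodic", {
  expect_equal(assign_register("EIAALEQ", 0), strsplit("abcdefg", "")[[1]])
  expect_equal(assign_register("EIAALEQEIAALEQ", 0),
               rep(strsplit("abcdefg", "")[[1]], 2))
  # property: pure function of (offset, index), period 7, offset shift
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(7:40, 1)
    seqc <- paste(sample(c("A", "E", "K", "L", "S"), n, TRUE), collapse = "")
    off <- sample(0:6, 1)
    reg <- assign_register(seqc, off)
    i <- sample(seq_len(n - 7), 1)
    expect_identical(reg[i], reg[i + 7])
    reg_shift <- assign_register(seqc, (off + 1) %% 7)
    expect_identical(reg_shift[seq_len(n - 1)], reg[1 + seq_len(n - 1)])
  }
})

test_that("non-canonical residues are rejected with the offending index", {
  expect_error(assign_register("EIZALEQ", 0), "position 3")
  expect_error(registered_peptide("x", "ALJ"), "position 3")
})

test_that("the kinase motif lands with Ser at a of heptad 2 and Arg at e/f of heptad 1", {
  p <- cc_switch_peptides()
  b_rrs <- insert_kinase_motif(p[["CC-Di-B_N4"]], "RRxS", "a", 2)
  expect_identical(b_rrs$sequence, p[["CC-Di-B_RRS"]]$sequence)
  reg <- registers(b_rrs)
  hept <- heptad_index(b_rrs)
  res <- strsplit(b_rrs$sequence, "")[[1]]
  i_s <- which(res == "S" & reg == "a")
  expect_length(i_s, 1)
  expect_equal(hept[i_s], 2)
  i_r <- which(res == "R")
  expect_setequal(reg[i_r], c("e", "f"))
  expect_true(all(hept[i_r] == 1))
  # differs from parent only at the non-x motif positions
  parent_res <- strsplit(p[["CC-Di-B_N4"]]$sequence, "")[[1]]
  expect_equal(sum(parent_res != res), 3) # R, R, S; 'x' kept the parent K
})

test_that("all-x motifs are identity and overruns are errors", {
  p <- cc_switch_peptides()[["CC-Di-B_N4"]]
  expect_identical(insert_kinase_motif(p, "xxxx", "a", 2)$sequence, p$sequence)
  expect_error(insert_kinase_motif(toy_peptide(), "RRxS", "a", 2), "overrun")
})

test_that("register placement round-trips for all valid anchors", {
  p <- cc_switch_peptides()[["CC-Di-B_N4"]]
  for (hept in 2:4) {
    out <- insert_kinase_motif(p, "RRxS", "a", hept)
    reg <- registers(out)
    hx <- heptad_index(out)
    res <- strsplit(out$sequence, "")[[1]]
    i_acc <- which(reg == "a" & hx == hept)
    expect_identical(res[i_acc], "S")
    expect_identical(res[i_acc - 3], "R")
    expect_identical(reg[i_acc - 3], "e")
    expect_identical(res[i_acc - 2], "R")
    expect_identical(reg[i_acc - 2], "f")
  }
})

test_that("substitution at a register address changes exactly one residue", {
  p <- cc_switch_peptides()
  a_s <- substitute_at_register(p[["CC-Di-A_N4"]], "a", 2, "S")
  expect_identical(a_s$sequence, p[["CC-Di-A_S"]]$sequence)
  expect_equal(sum(strsplit(a_s$sequence, "")[[1]] !=
                     strsplit(p[["CC-Di-A_N4"]]$sequence, "")[[1]]), 1)
  expect_identical(registers(a_s), registers(p[["CC-Di-A_N4"]]))
  # idempotence and involution
  same <- substitute_at_register(p[["CC-Di-A_N4"]], "a", 1, "I")
  expect_identical(same$sequence, p[["CC-Di-A_N4"]]$sequence)
  back <- substitute_at_register(a_s, "a", 2, "I")
  expect_identical(back$sequence, p[["CC-Di-A_N4"]]$sequence)
  expect_error(substitute_at_register(p[["CC-Di-A_N4"]], "a", 9, "S"), "outside")
})

test_that("helical wheel geometry: distinct angles, 7-periodicity, a/d adjacency", {
  w7 <- helical_wheel(toy_peptide("EIAALEQ", 0))
  expect_equal(nrow(w7), 7)
  expect_equal(length(unique(round(w7$angle_deg, 6))), 7)
  expect_equal(sort(diff(sort(w7$angle_deg))), rep(360 / 7, 6), tolerance = 1e-6)
  w14 <- helical_wheel(toy_peptide("EIAALEQEIAALEQ", 0))
  expect_equal(w14$angle_deg[1:7], w14$angle_deg[8:14], tolerance = 1e-9)
  # a and d occupy adjacent sectors on the 3.5-residue wheel
  ang_a <- w7$angle_deg[w7$register == "a"]
  ang_d <- w7$angle_deg[w7$register == "d"]
  delta <- abs(ang_a - ang_d) %% 360
  expect_equal(min(delta, 360 - delta), 360 / 7, tolerance = 1e-6)
  expect_error(helical_wheel(toy_peptide("AAAAA", 0)), "at least 7")
})

test_that("hydrophobic moment: symmetry zero, oracle equality, amphipathic enrichment", {
  # full heptads of one residue: vectors cancel
  expect_lt(hydrophobic_moment(toy_peptide("LLLLLLLLLLLLLL", 0))$moment, 1e-9)
  # brute-force vector sum oracle on an arbitrary sequence
  seqc <- "MSKLWSKISKLFS"
  th <- (seq_len(nchar(seqc)) - 1) * (360 / 3.5) * pi / 180
  h <- ccswitch:::HYDRO_EISENBERG[strsplit(seqc, "")[[1]]]
  expected <- sqrt(sum(h * cos(th))^2 + sum(h * sin(th))^2)
  expect_equal(hydrophobic_moment(seqc)$moment, expected, tolerance = 1e-12)
  # the synthetic MTS beats almost all scrambles of itself
  mts <- synthetic_mts()
  m0 <- hydrophobic_moment(mts)$moment
  set.seed(2024)
  res <- strsplit(mts$sequence, "")[[1]]
  shuffled <- replicate(1000, {
    hydrophobic_moment(paste(sample(res), collapse = ""))$moment
  })
  expect_gt(m0, mean(shuffled))
  expect_gt(mean(m0 > shuffled), 0.95)
  # sign reversal of the scale flips direction but keeps the magnitude
  m_neg <- hydrophobic_moment(seqc, scale = -ccswitch:::HYDRO_EISENBERG)
  expect_equal(m_neg$moment, expected, tolerance = 1e-12)
  expect_error(hydrophobic_moment(seqc, scale = c(A = 1)), "lacks residue")
})

test_that("molecular mass matches the frozen residue-table oracle", {
  expect_equal(molecular_mass("G"), 75.07, tolerance = 0.01)
  set.seed(7)
  for (rep in 1:100) {
    seqc <- paste(sample(names(ORACLE_AA_AVG), sample(5:40, 1), TRUE),
                  collapse = "")
    expect_equal(molecular_mass(seqc), oracle_mass_avg(seqc),
                 tolerance = 0.01)
  }
  # strictly increasing in length
  expect_gt(molecular_mass("GG"), molecular_mass("G"))
})

test_that("modification deltas: phospho, acetyl, amide", {
  p <- cc_switch_peptides()
  d <- molecular_mass(p[["CC-Di-B_RRpS"]]) - molecular_mass(p[["CC-Di-B_RRS"]])
  expect_equal(d, 79.98, tolerance = 0.01)
  plain <- registered_peptide("x", "GASK")
  acet <- registered_peptide("x", "GASK", n_term_mod = "acetyl")
  amid <- registered_peptide("x", "GASK", c_term_mod = "amide")
  expect_equal(molecular_mass(acet) - molecular_mass(plain), 42.037,
               tolerance = 0.001)
  expect_equal(molecular_mass(amid) - molecular_mass(plain), -0.985,
               tolerance = 0.001)
  expect_error(registered_peptide("x", "GASK",
                                  sidechain_mods = data.frame(index = 1, mod = "phospho")),
               "requires S, T or Y")
})

test_that("monoisotopic convention and Met-cleaved fusion masses", {
  expect_equal(molecular_mass("G", "monoisotopic"), 75.032, tolerance = 0.001)
  fm <- fusion_masses("MGASK")
  expect_equal(unname(fm["met_retained"] - fm["met_cleaved"]),
               131.196, tolerance = 0.001)
  expect_true(is.na(fusion_masses("GASK")["met_cleaved"]))
})

test_that("epsilon280 is the Trp/Tyr count rule and is additive", {
  expect_equal(epsilon280("AAAA"), 0)
  expect_equal(epsilon280("W"), 5690)
  expect_equal(epsilon280("WWYYY"), 2 * 5690 + 3 * 1280)
  expect_equal(epsilon280(paste0("WAY", "KWW")),
               epsilon280("WAY") + epsilon280("KWW"))
})

test_that("FASTA round trip preserves sequence, register and modifications", {
  p <- cc_switch_peptides()
  path <- tempfile(fileext = ".fasta")
  write_peptides_fasta(p, path)
  back <- read_peptides_fasta(path)
  expect_equal(length(back), length(p))
  for (nm in names(p)) {
    expect_identical(back[[nm]]$sequence, p[[nm]]$sequence)
    expect_identical(back[[nm]]$register_offset, p[[nm]]$register_offset)
    expect_identical(back[[nm]]$core, p[[nm]]$core)
    expect_identical(back[[nm]]$n_term_mod, p[[nm]]$n_term_mod)
    expect_identical(back[[nm]]$c_term_mod, p[[nm]]$c_term_mod)
  }
  expect_equal(back[["CC-Di-B_RRpS"]]$sidechain_mods$index,
               p[["CC-Di-B_RRpS"]]$sidechain_mods$index)
})
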