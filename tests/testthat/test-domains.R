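# wrky_domains: heptapeptide detection, zinc-finger parsing, domain assembly.

test_that("find_heptapeptides matches the worked examples", {
  hit <- find_heptapeptides("AAWRKYGQKAA")
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, 2L)
  expect_equal(hit$motif, "WRKYGQK")
  expect_equal(hit$mismatches, 0L)
  expect_true(hit$canonical)

  expect_equal(nrow(find_heptapeptides("AAAAAAAAAA")), 0)

  var <- find_heptapeptides("MWRKYATNCA")
  expect_equal(var$motif, "WRKYATN")
  expect_equal(var$mismatches, 3L)
  expect_false(var$canonical)

  # tolerance boundary: 4 substitutions outside anchors is rejected
  expect_equal(nrow(find_heptapeptides("WAKYAAA", max_mismatches = 3)), 0)
  expect_equal(nrow(find_heptapeptides("WAKYAAA", max_mismatches = 4)), 1)
})

test_that("find_heptapeptides validates input and never matches X", {
  expect_equal(nrow(find_heptapeptides("")), 0)
  expect_error(find_heptapeptides("AABAA"), "position 3")
  expect_error(find_heptapeptides("WRKYGQ*"), "position 7")
  # X at an anchor kills the window; X elsewhere counts as a mismatch
  expect_equal(nrow(find_heptapeptides("XRKYGQK")), 0)
  hit <- find_heptapeptides("WRKYGQX")
  expect_equal(hit$mismatches, 1L)
})

test_that("find_heptapeptides agrees with brute-force enumeration", {
  set.seed(101)
  for (rep in 1:40) {
    s <- random_protein(sample(20:250, 1), with_x = TRUE)
    mm <- sample(0:3, 1)
    expect_equal(find_heptapeptides(s, mm), oracle_hepta(s, mm),
                 ignore_attr = TRUE)
  }
  # overlap-rich sequence: every window reported
  s <- strrep("WRKYWRKY", 5)
  expect_equal(find_heptapeptides(s, 3), oracle_hepta(s, 3),
               ignore_attr = TRUE)
})

test_that("find_zinc_finger reproduces the printed signature grammar", {
  cases <- list(
    list(seq = paste0("C", strrep("A", 4), "C", strrep("A", 22), "HAH"),
         sig = "C-X4-C-X22-HXH", type = "CCHH"),
    list(seq = paste0("C", strrep("A", 7), "C", strrep("A", 23), "HAC"),
         sig = "C-X7-C-X23-HXC", type = "CCHC"),
    list(seq = paste0("C", strrep("A", 4), "C", strrep("A", 23), "HAY"),
         sig = "C-X4-C-X23-HXY", type = "CCHY"))
  for (cs in cases) {
    zf <- find_zinc_finger(cs$seq)
    expect_equal(zf$signature, cs$sig)
    expect_equal(zf$finger_type, cs$type)
    expect_equal(zf$start, 0L)
  }
  expect_null(find_zinc_finger("AAAA"))
  # anomalous compact finger admitted by the configured envelope
  zf <- find_zinc_finger(paste0("C", strrep("A", 3), "C", strrep("A", 5), "HAC"))
  expect_equal(zf$signature, "C-X3-C-X5-HXC")
})

test_that("find_zinc_finger tie-breaking prefers start, then compact spacers", {
  # C at 0 can pair with C at 4 (a=3) or C at 8 (a=7); smallest spacer1 wins
  s <- paste0("CAAAC", "AAAC", strrep("A", 5), "HAH", strrep("A", 30), "HAH")
  zf <- find_zinc_finger(s)
  expect_equal(zf$start, 0L)
  expect_equal(zf$spacer1, 3L)
  # from_index skips earlier candidates entirely
  zf2 <- find_zinc_finger(s, from_index = 1)
  expect_equal(zf2$start, 4L)
})

test_that("find_zinc_finger agrees with brute-force enumeration", {
  set.seed(202)
  pool <- c("A", "C", "H", "Y", "G")    # anchor-rich alphabet
  for (rep in 1:60) {
    s <- paste(sample(pool, sample(30:120, 1), replace = TRUE), collapse = "")
    from <- sample(0:5, 1)
    got <- find_zinc_finger(s, from)
    want <- oracle_zf(s, from)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$start, want$start)
      expect_equal(got$spacer1, want$spacer1)
      expect_equal(got$spacer2, want$spacer2)
      expect_equal(got$terminal, want$terminal)
    }
  }
})

test_that("signature rendering round-trips", {
  for (a in 3:7) for (b in c(5, 22, 23, 27)) for (t in c("H", "C", "Y")) {
    sig <- render_signature(a, b, t)
    p <- parse_signature(sig)
    expect_equal(p$spacer1, a)
    expect_equal(p$spacer2, b)
    expect_equal(p$terminal, t)
  }
  expect_error(parse_signature("C-X4-C-X22-HXQ"), "unparseable")
})

test_that("assemble_domains pairs heptapeptides with fingers and labels N/C", {
  block <- function(s1, s2, term) {
    paste0("WRKYGQK", strrep("A", 10), "C", strrep("A", s1), "C",
           strrep("A", s2), "H", "A", term)
  }
  two <- paste0("MA", block(4, 22, "H"), strrep("A", 20), block(4, 23, "H"))
  dom <- assemble_domains(two)
  expect_equal(nrow(dom), 2)
  expect_equal(dom$terminal_position, c("N", "C"))
  expect_equal(dom$signature, c("C-X4-C-X22-HXH", "C-X4-C-X23-HXH"))

  one <- paste0("MA", block(7, 23, "C"))
  d1 <- assemble_domains(one)
  expect_equal(d1$terminal_position, "only")
  expect_equal(d1$finger_type, "CCHC")

  # unvalidated variant heptapeptide: no downstream Cys, no domain
  expect_equal(nrow(assemble_domains("MWRKYATNAAAAAAAA")), 0)
  # canonical heptapeptide without a finger is dropped too
  expect_equal(nrow(assemble_domains("MWRKYGQKAAAAAAAA")), 0)
})

test_that("linker_max bounds the heptapeptide-finger pairing", {
  far <- paste0("WRKYGQK", strrep("A", 130), "C", strrep("A", 4), "C",
                strrep("A", 22), "HAH")
  expect_equal(nrow(assemble_domains(far)), 0)
  cfg <- wrky_config(linker_max = 200)
  expect_equal(nrow(assemble_domains(far, cfg)), 1)
})

test_that("planted synthetic proteomes are recovered exactly", {
  sim <- gen_proteome(c(I = 10, III = 10, IIc = 10), mutation_rate = 0,
                      seed = 77)
  doms <- scan_proteome(sim$proteins)
  for (id in names(sim$proteins)) {
    truth <- sim$truth[[id]]
    expect_equal(nrow(doms[[id]]), length(truth$hep_starts), info = id)
    expect_equal(doms[[id]]$hep_start, truth$hep_starts, info = id)
    expect_equal(doms[[id]]$zf_start, truth$zf_starts, info = id)
    expect_equal(doms[[id]]$motif, truth$motifs, info = id)
  }
  rep <- identify_wrky(sim$proteins)
  expect_equal(nrow(rep), 30)
  expect_equal(rep$n_domains[rep$protein_id == "SYN_I_01"], 2)
})

test_that("detection is deterministic", {
  set.seed(7)
  s <- random_protein(300)
  expect_identical(assemble_domains(s), assemble_domains(s))
})
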