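ctd_tab <- ctd_property_table()

test_that("shipped property table partitions the alphabet 8 x 3 ways", {
  expect_length(ctd_tab, 8L)
  for (p in names(ctd_tab)) {
    expect_length(ctd_tab[[p]], 3L)
    expect_setequal(unname(unlist(ctd_tab[[p]])), AA_ALPHABET)
  }
  expect_setequal(unname(unlist(AA_GROUPS5)), AA_ALPHABET)
})

test_that("AAC counts residue frequencies", {
  v <- encode_aac("AAAA")
  expect_equal(unname(v["A"]), 1)
  expect_equal(sum(v), 1)
  expect_equal(unname(encode_aac("ACDEFGHIKLMNPQRSTVWY")),
               rep(0.05, 20))
  v2 <- encode_aac("AC")
  expect_equal(unname(v2[c("A", "C", "D")]), c(0.5, 0.5, 0))
  expect_error(encode_aac(""), "empty")
})

test_that("grouped compositions match hand-enumerated examples", {
  g <- encode_gaac("GAVLMI")
  expect_equal(unname(g["c1"]), 1)
  expect_equal(unname(encode_gaac("FD")[c("c2", "c4")]), c(0.5, 0.5))
  expect_equal(unname(encode_gaac("KRHDE")[c("c3", "c4")]), c(0.6, 0.4))

  expect_equal(unname(encode_gdpc("GF")["c1.c2"]), 1)
  expect_equal(unname(encode_gdpc("GGG")["c1.c1"]), 1)
  d <- encode_gdpc("GFKD")
  expect_equal(unname(d[c("c1.c2", "c2.c3", "c3.c4")]), rep(1 / 3, 3))
  expect_equal(sum(d), 1)
  expect_error(encode_gdpc("G"), "length >= 2")

  expect_equal(unname(encode_gtpc("GFK")["c1.c2.c3"]), 1)
  expect_equal(unname(encode_gtpc("GGGG")["c1.c1.c1"]), 1)
  t3 <- encode_gtpc("GFKD")
  expect_equal(unname(t3[c("c1.c2.c3", "c2.c3.c4")]), c(0.5, 0.5))
  expect_error(encode_gtpc("GF"), "length >= 3")
})

test_that("CTD matches hand-derived values on a 3-mer and the brute-force oracle", {
  # ARN under hydrophobicity (polar RKEDQN = g1, neutral GASTPHY = g2):
  # A->g2, R->g1, N->g1
  v <- encode_ctd("ARN", ctd_tab)
  expect_length(v, 168L)
  expect_equal(unname(v[paste0("hydrophobicity.C.", c("g1", "g2", "g3"))]),
               c(2 / 3, 1 / 3, 0))
  expect_equal(unname(v[paste0("hydrophobicity.T.", c("g1g2", "g1g3", "g2g3"))]),
               c(0.5, 0, 0))
  expect_equal(unname(v[paste0("hydrophobicity.D.g1.",
                               c("first", "p25", "p50", "p75", "last"))]),
               c(2 / 3, 2 / 3, 2 / 3, 1, 1))
  expect_equal(unname(v[paste0("hydrophobicity.D.g2.",
                               c("first", "p25", "p50", "p75", "last"))]),
               rep(1 / 3, 5))
  expect_equal(unname(v[paste0("hydrophobicity.D.g3.",
                               c("first", "p25", "p50", "p75", "last"))]),
               rep(0, 5))

  # homopolymer: one C component 1, no transitions, D only for A's group
  h <- encode_ctd("AAAAAAAAAA", ctd_tab)
  for (p in names(ctd_tab)) {
    grp_a <- names(ctd_tab[[p]])[vapply(ctd_tab[[p]], function(g)
      "A" %in% g, logical(1))]
    cvals <- h[paste0(p, ".C.", c("g1", "g2", "g3"))]
    expect_equal(unname(cvals[paste0(p, ".C.", grp_a)]), 1)
    expect_equal(sum(cvals), 1)
    expect_equal(unname(h[paste0(p, ".T.", c("g1g2", "g1g3", "g2g3"))]),
                 rep(0, 3))
  }

  # full agreement with the independent enumeration oracle
  set.seed(101)
  for (i in 1:25) {
    s <- random_peptide(3, 30)
    got <- encode_ctd(s, ctd_tab)
    want <- unlist(lapply(names(ctd_tab), function(p)
      ctd_oracle_one(s, ctd_tab[[p]])))
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("CTD is invariant to within-group residue substitution, per property", {
  set.seed(77)
  for (p in names(ctd_tab)) {
    s <- random_peptide(10, 20)
    ch <- strsplit(s, "")[[1]]
    swapped <- vapply(ch, function(a) {
      grp <- ctd_tab[[p]][[which(vapply(ctd_tab[[p]], function(g)
        a %in% g, logical(1)))]]
      sample(grp, 1)
    }, character(1))
    s2 <- paste(swapped, collapse = "")
    blocks <- grep(paste0("^", p, "\\."), names(encode_ctd(s, ctd_tab)))
    expect_equal(encode_ctd(s, ctd_tab)[blocks],
                 encode_ctd(s2, ctd_tab)[blocks])
  }
})

test_that("ASDC matches examples and the brute-force pair-counting oracle", {
  v <- encode_asdc("AC")
  expect_equal(unname(v["ASDC.AC"]), 1)
  expect_equal(sum(v), 1)
  v2 <- encode_asdc("ACA")
  expect_equal(unname(v2[c("ASDC.AC", "ASDC.AA", "ASDC.CA")]), rep(1 / 3, 3))
  expect_error(encode_asdc("A"), "length >= 2")

  set.seed(303)
  for (i in 1:100) {
    s <- random_peptide(8, 30)
    expect_equal(unname(encode_asdc(s)), unname(asdc_oracle(s)),
                 tolerance = 1e-12)
  }
})

test_that("PAAC has 20 + lambda components summing to 1; homopolymer collapses", {
  v <- encode_paac("ACDEFGHIKL", lambda = 2)
  expect_length(v, 22L)
  expect_equal(sum(v), 1, tolerance = 1e-12)

  h <- encode_paac("AAAAA", lambda = 2)
  expect_equal(unname(h["PAAC.f.A"]), 1)
  expect_equal(unname(h[c("PAAC.theta.1", "PAAC.theta.2")]), c(0, 0))

  v5 <- encode_paac("ACDEFGHIKL", lambda = 5)
  expect_length(v5, 25L)
  expect_error(encode_paac("ACD", lambda = 3), "length >= 4")

  # theta uses standardized properties: mean 0, population SD 1
  props <- paac_property_values()
  expect_equal(unname(colMeans(props)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(props, 2, function(x) mean(x^2))), rep(1, 3),
               tolerance = 1e-12)
})

test_that("encoders are pure functions of the sequence", {
  s <- "ACDEFGHIKLMNP"
  expect_identical(encode_gpsd(s, ctd_tab), encode_gpsd(s, ctd_tab))
  expect_identical(encode_paac(s), encode_paac(s))
  ds <- peptide_dataset(c("x", "y"), c(s, s))
  X <- encode_dataset(ds)
  expect_equal(unname(X["x", ]), unname(X["y", ]))
})

test_that("dimensionality contract holds across random peptides", {
  set.seed(11)
  for (i in 1:50) {             # spot sample; the full 1000 runs in acceptance
    s <- random_peptide(8, 30)
    expect_length(encode_gaac(s), 5L)
    expect_length(encode_gdpc(s), 25L)
    expect_length(encode_gtpc(s), 125L)
    expect_length(encode_gaapc(s), 155L)
    expect_length(encode_asdc(s), 400L)
    expect_length(encode_aac(s), 20L)
    expect_length(encode_ctd(s, ctd_tab), 168L)
    expect_length(encode_gpsd(s, ctd_tab), 188L)
    expect_length(encode_paac(s), 22L)
  }
})

test_that("composition blocks sum to 1 and GPSD/GAAPC obey concatenation contracts", {
  set.seed(21)
  for (i in 1:20) {
    s <- random_peptide(8, 30)
    expect_equal(sum(encode_aac(s)), 1, tolerance = 1e-9)
    expect_equal(sum(encode_gaac(s)), 1, tolerance = 1e-9)
    expect_equal(sum(encode_gdpc(s)), 1, tolerance = 1e-9)
    expect_equal(sum(encode_gtpc(s)), 1, tolerance = 1e-9)
    expect_equal(sum(encode_asdc(s)), 1, tolerance = 1e-9)
    expect_equal(unname(encode_gpsd(s, ctd_tab)[1:20]),
                 unname(encode_aac(s)))
    expect_equal(unname(encode_gaapc(s)[1:5]), unname(encode_gaac(s)))
  }
})

test_that("encode_dataset builds the 365-column hybrid matrix with unique names", {
  ds <- generate_peptides(6, 6, seed = 2)
  X <- encode_dataset(ds, schemes = c("gpsd", "gaapc", "paac"))
  expect_equal(dim(X), c(12L, 365L))
  expect_false(anyDuplicated(colnames(X)) > 0)
  expect_equal(rownames(X), ds$id)

  short <- peptide_dataset(c("ok", "tiny"), c("ACDEF", "AC"))
  expect_error(encode_dataset(short, schemes = "gaapc"), "tiny")
})

test_that("concat_features validates sample alignment and name uniqueness", {
  ds <- generate_peptides(4, 4, seed = 8)
  A <- encode_dataset(ds, "gpsd")
  B <- encode_dataset(ds, "gaapc")
  AB <- concat_features(list(A, B))
  expect_equal(ncol(AB), 343L)
  expect_identical(concat_features(list(A)), A)
  Bperm <- B[rev(seq_len(nrow(B))), ]
  expect_error(concat_features(list(A, Bperm)), "sample ids differ")
  expect_error(concat_features(list(A, A)), "duplicate feature names")
})
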