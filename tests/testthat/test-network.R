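test_that("connection blocks have the right density and no autapses", {
  set.seed(1)
  expect_true(all(!build_connection_block(50, 50, 0)))
  full <- build_connection_block(100, 100, 1, same_population = TRUE)
  expect_equal(sum(full), 9900)
  expect_true(all(!diag(full)))
  blk <- build_connection_block(800, 100, 0.3)
  mu <- 800 * 100 * 0.3
  sdv <- sqrt(800 * 100 * 0.3 * 0.7)
  expect_lt(abs(sum(blk) - mu), 3 * sdv)
  expect_error(build_connection_block(10, 10, 1.5), "probability")
})

test_that("weight draws follow the per-type normal distributions", {
  cts <- default_cell_types()
  set.seed(2)
  w_rs <- sample_weights(cts$RS, 1e5)
  expect_lt(abs(mean(w_rs) - 1), 3 * 0.5 / sqrt(1e5))
  expect_equal(sd(w_rs), 0.5, tolerance = 0.02)
  w_fs <- sample_weights(cts$FS, 1e5)
  expect_lt(abs(mean(w_fs) + 2), 3 * 1 / sqrt(1e5))
  expect_equal(sd(w_fs), 1, tolerance = 0.02)
  expect_length(sample_weights(cts$RS, 0), 0)
  expect_true(all(sample_weights(cts$LTS, 1e4, clip_sign = TRUE) <= 0))
})

test_that("motif enumeration yields 20 unique motifs with the named anchors", {
  motifs <- enumerate_motifs()
  expect_length(motifs, 20)
  three_cell <- Filter(function(m) m$has_fs && m$has_lts, motifs)
  expect_length(three_cell, 18)

  # motif I: two-cell RS-FS with all four edges
  expect_setequal(motifs$I$edges, c("RS->RS", "RS->FS", "FS->RS", "FS->FS"))
  expect_false(motifs$I$has_lts)
  # motif II: two-cell RS-LTS, no FS edges
  expect_false(motifs$II$has_fs)
  expect_true(motifs$II$has_lts)
  # motif VIII: disinhibition with external drive and FS->LTS
  expect_true(all(c("RS->LTS", "LTS->FS", "FS->LTS") %in% motifs$VIII$edges))
  expect_false("LTS->RS" %in% motifs$VIII$edges)
  expect_equal(motifs$VIII$lts_input_regime, "both")
  # motif IV/V: disinhibition without/with external drive, no FS->LTS
  for (m in list(motifs$IV, motifs$V)) {
    expect_true("LTS->FS" %in% m$edges)
    expect_false("LTS->RS" %in% m$edges)
    expect_false("FS->LTS" %in% m$edges)
  }
  expect_equal(motifs$IV$lts_input_regime, "local_only")
  expect_equal(motifs$V$lts_input_regime, "both")
  # motifs IX and XII: external-only input with FS inhibition of LTS
  for (m in list(motifs$IX, motifs$XII)) {
    expect_equal(m$lts_input_regime, "external_only")
    expect_true("FS->LTS" %in% m$edges)
    expect_false("RS->LTS" %in% m$edges)
  }
  expect_true("LTS->RS" %in% motifs$IX$edges)
  expect_false("LTS->FS" %in% motifs$IX$edges)

  # all three-cell motifs keep the four RS/FS edges; RS->LTS iff local input
  for (m in three_cell) {
    expect_true(all(c("RS->RS", "RS->FS", "FS->RS", "FS->FS") %in% m$edges))
    expect_equal("RS->LTS" %in% m$edges,
                 m$lts_input_regime %in% c("local_only", "both"))
  }
  # no motif contains LTS->LTS and the edge/regime combinations are unique
  expect_false(any(vapply(motifs, function(m) "LTS->LTS" %in% m$edges, TRUE)))
  keys <- vapply(motifs, function(m)
    paste(paste(sort(m$edges), collapse = ","), m$lts_input_regime), "")
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("motif library serializes to JSON round-trip", {
  js <- motifs_to_json()
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_length(parsed, 20)
  expect_equal(parsed[[8]]$motif_id, "VIII")
  expect_equal(sort(unlist(parsed[[1]]$edges)),
               sort(get_motif("I")$edges))
})

test_that("assembled networks honour motif edges and Table probabilities", {
  set.seed(3)
  conn1 <- assemble_network(get_motif("I"))
  expect_setequal(names(conn1$blocks), get_motif("I")$edges)
  conn2 <- assemble_network(get_motif("II"))
  expect_false(any(grepl("FS", names(conn2$blocks))))
  # realized densities close to Table values
  dens <- length(conn2$blocks[["RS->LTS"]]$w) / (800 * 200)
  expect_equal(dens, 0.10, tolerance = 0.05)
  dens2 <- length(conn2$blocks[["LTS->RS"]]$w) / (200 * 800)
  expect_equal(dens2, 0.40, tolerance = 0.03)
})

test_that("seed stability and ablation locality hold", {
  set.seed(10); cA <- assemble_network(get_motif("VIII"))
  set.seed(10); cB <- assemble_network(get_motif("VIII"))
  expect_identical(cA, cB)
  cC <- ablate_edges(cA, "FS->FS")
  expect_null(cC$blocks[["FS->FS"]])
  for (e in setdiff(names(cA$blocks), "FS->FS"))
    expect_identical(cC$blocks[[e]], cA$blocks[[e]])
})
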