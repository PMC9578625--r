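# Chain mapping: candidate enumeration, sequence filtering, manual
# baseline and structural exclusions.

# small world shared by the tests below
chain_world <- local({
  model <- separated_class_model(c("A", "G", "L", "S", "T", "V"), sep = 12)
  prot <- sample_protein(model, 120L, seed = 91L, id = "cw")
  train <- sample_protein(model, 400L, seed = 92L, id = "cwtr")$spins
  cl <- classify_spins(prot$spins, train, "iii",
                       allowed_types = model$classes)
  list(model = model, prot = prot, train = train, cl = cl)
})

test_that("candidate counts, probabilities and ordering behave", {
  w <- chain_world
  ch <- ss_chain("c1", w$prot$spins$id[10:12])
  cand <- enumerate_candidates(ch, w$cl, inclusion_threshold = 0,
                               top_k = Inf)
  K <- length(w$cl$classes)
  # product structure: with threshold 0 the full product set appears,
  # minus structurally impossible types at complete positions
  expect_true(nrow(cand) <= K^3)
  # probabilities sum to 1 over the full uncapped set
  expect_equal(sum(cand$joint_probability), 1, tolerance = 1e-9)
  # sorted non-increasing
  expect_true(all(diff(cand$joint_probability) <= 1e-15))
  # top candidate is the concatenated argmax when positions are sharp
  truth <- w$prot$spins$residue_type[10:12]
  expect_equal(cand$sequence[1], paste(truth, collapse = ""))

  # hand-sized check: retained sets of sizes (2, 1) give 2 candidates
  # with product probabilities
  post <- matrix(c(0.7, 0.3, 0, 1.0, 0, 0), nrow = 2, byrow = TRUE,
                 dimnames = list(c("s1", "s2"), c("A", "G", "L")))
  fake <- list(posteriors = post, classes = colnames(post))
  ch2 <- ss_chain("c2", c("s1", "s2"))
  cand2 <- enumerate_candidates(ch2, fake, inclusion_threshold = 0.05)
  expect_equal(nrow(cand2), 2L)
  expect_equal(cand2$joint_probability, c(0.7, 0.3))
  expect_equal(cand2$sequence, c("AA", "GA"))
})

test_that("raising the threshold only prunes, never adds", {
  w <- chain_world
  ch <- ss_chain("c3", w$prot$spins$id[20:23])
  prev <- NULL
  for (thr in c(0, 0.001, 0.01, 0.1, 0.5)) {
    cand <- enumerate_candidates(ch, w$cl, inclusion_threshold = thr,
                                 top_k = Inf)
    if (!is.null(prev))
      expect_true(all(cand$sequence %in% prev$sequence))
    prev <- cand
  }
})

test_that("position-empty fallback and the candidate cap warn", {
  post <- matrix(c(0.4, 0.3, 0.3), 1, dimnames = list("s1", c("A", "G", "L")))
  fake <- list(posteriors = post, classes = colnames(post))
  expect_warning(
    cand <- enumerate_candidates(ss_chain("c", "s1"), fake,
                                 inclusion_threshold = 0.9),
    "single best")
  expect_equal(cand$sequence, "A")
  post2 <- matrix(1 / 3, 4, 3,
                  dimnames = list(paste0("s", 1:4), c("A", "G", "L")))
  fake2 <- list(posteriors = post2, classes = colnames(post2))
  expect_warning(
    cand2 <- enumerate_candidates(ss_chain("c", paste0("s", 1:4)), fake2,
                                  inclusion_threshold = 0, max_candidates = 10L),
    "cap")
  expect_equal(nrow(cand2), 10L)
})

test_that("sequence filtering finds all overlapping occurrences", {
  seqp <- protein_seq("AAGLSAAGLSAA", id = "t")
  cand <- data.frame(sequence = c("GLS", "AA", "QQQ"),
                     joint_probability = c(0.5, 0.3, 0.2),
                     stringsAsFactors = FALSE)
  out <- filter_by_sequence(cand, seqp)
  expect_equal(out$positions[1], "3,8")
  expect_equal(out$n_positions[2], 3L)       # AA at 1, 6, 11
  expect_equal(out$positions[2], "1,6,11")
  expect_true(out$discarded[3])
  expect_equal(out$joint_probability, cand$joint_probability)  # untouched
  # genuinely overlapping occurrences are all reported
  out2 <- filter_by_sequence(
    data.frame(sequence = "AA", joint_probability = 1), protein_seq("AAAA"))
  expect_equal(out2$positions, "1,2,3")
})

test_that("map_chain resolves planted chains and reports failures", {
  w <- chain_world
  chains <- sample_chains(w$prot$sequence, w$prot$spins, n_chains = 8L,
                          length_range = c(4L, 6L), seed = 93L)
  for (ch in chains) {
    rep <- map_chain(ch, w$cl, w$prot$sequence)
    expect_true(attr(rep, "unambiguous"))
    expect_equal(attr(rep, "member_start"), attr(ch, "start"))
    # discarded candidates stay in the report
    expect_true(all(c("positions", "discarded") %in% names(rep)))
  }
  # a chain whose true type is excluded at one position: no survivor
  # containing the truth (the manual-intervention failure mode)
  post <- matrix(c(0.5, 0.5, 0, 1, 0, 0), nrow = 2, byrow = TRUE,
                 dimnames = list(c("s1", "s2"), c("A", "G", "L")))
  fake <- list(posteriors = post, classes = colnames(post))
  repF <- map_chain(ss_chain("cf", c("s1", "s2")), fake,
                    protein_seq("LALA", id = "x"))
  expect_equal(attr(repF, "n_survivors"), 0L)
  expect_false(attr(repF, "unambiguous"))
})

test_that("manual baseline recognizes G/A/S/T and defaults to X", {
  sp <- spin_table(
    id = c("g", "a", "t", "w"),
    residue_type = c("G", "A", "T", "W"),
    CA = c(45.2, 52.4, 61.9, 57.4),
    CB = c(NA, 19.2, 69.5, 29.5),
    HB = c(NA, 1.4, 4.2, 3.2),
    warn = FALSE)
  ch <- ss_chain("m", c("g", "a", "t", "w"))
  expect_equal(manual_baseline(ch, sp), c("G", "A", "T", "X"))
})

test_that("structural exclusions follow the Hbeta/Cbeta rules", {
  df <- data.frame(id = c("x1", "x2", "x3"),
                   CA = c(56, 56, 56),
                   CB = c(30.1, NA, NA),
                   HB2 = c(NA, 1.8, NA),
                   HB3 = c(NA, 1.9, NA),
                   stringsAsFactors = FALSE)
  ex <- structural_exclusions(as_spin_table(df, warn = FALSE))
  expect_equal(ex$x1, "G")                       # CB present
  expect_setequal(ex$x2, c("G", "A", "I", "T", "V"))  # two distinct HB
  expect_equal(ex$x3, character(0))              # no beta information
  # exclusions zero posteriors before renormalization
  w <- chain_world
  q <- as_spin_table(as.data.frame(w$prot$spins)[1:3, ], warn = FALSE)
  cl <- classify_spins(q, w$train, "i",
                       allowed_types = w$model$classes,
                       exclusions = stats::setNames(list("G"), q$id[1]))
  expect_equal(cl$posteriors[1, "G"], 0)
  expect_equal(sum(cl$posteriors[1, ]), 1)
})
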