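ann <- load_default_annotations()

test_that("span lengths match the fibril protein bookkeeping", {
  expect_equal(span_length(residue_span(2, 116)), 115)  # Ser2-Ser116
  expect_equal(span_length(residue_span(60, 71)), 12)   # A/B difference
  expect_equal(span_length(residue_span(7, 7)), 1)
  expect_error(residue_span(10, 5), "start")
  expect_error(residue_span(0, 5), "1-based")
})

test_that("default annotations satisfy their structural invariants", {
  for (conf in list(ann$A, ann$B)) {
    fp <- conf$fibril_protein_span
    expect_equal(span_length(fp), 115)
    # strands sit inside ordered spans
    for (i in seq_len(nrow(conf$strand_spans))) {
      s <- conf$strand_spans[i, ]
      expect_true(any(s$start >= conf$ordered_spans$start &
                        s$end <= conf$ordered_spans$end))
    }
    # ordered and disordered spans are disjoint and tile the protein
    res <- seq.int(fp$start, fp$end)
    n_ord <- vapply(res, function(p)
      sum(p >= conf$ordered_spans$start & p <= conf$ordered_spans$end),
      numeric(1))
    n_dis <- vapply(res, function(p)
      sum(p >= conf$disordered_spans$start & p <= conf$disordered_spans$end),
      numeric(1))
    expect_true(all(n_ord + n_dis == 1))
  }
  expect_equal(nrow(ann$A$strand_spans), 14)  # beta1-12 plus beta6', beta6''
  expect_equal(nrow(ann$B$strand_spans), 12)
  expect_equal(nrow(ann$mutations), 7)
})

test_that("positions classify by region as in the mutation discussion", {
  # Asn51Ser: inside the internal disordered segment of both conformations
  expect_equal(classify_position(51, ann$A), "disordered")
  expect_equal(classify_position(51, ann$B), "disordered")
  # Val135Gly: beyond Ser116, lost with the constant domain
  expect_equal(classify_position(135, ann$A), "cleaved-or-absent")
  expect_equal(classify_position(135, ann$B), "cleaved-or-absent")
  # Gly49Arg: buried in the N-terminal ordered core of both
  expect_equal(classify_position(49, ann$A), "ordered-core")
  expect_equal(classify_position(49, ann$B), "ordered-core")

  mut <- ann$mutations
  expect_true(all(mut$region_A[mut$name %in% c("Asn51Ser", "Val135Gly")] !=
                    "ordered-core"))
  expect_true(all(mut$region_B[mut$name %in% c("Asn51Ser", "Val135Gly")] !=
                    "ordered-core"))
  expect_error(classify_position(0, ann$A), ">= 1")
})

test_that("classification agrees with a brute-force span scan on 1..150", {
  for (conf in list(ann$A, ann$B)) {
    got <- classify_position(1:150, conf)
    want <- vapply(1:150, brute_classify, character(1), annotation = conf)
    expect_identical(got, want)
  }
})

test_that("A/B differences are confined to the 60-71 segment", {
  d <- diff_annotations(ann$A, ann$B)
  expect_gt(nrow(d), 0)
  expect_true(all(d$start >= 60 & d$end <= 71))
  # indistinguishable over both shared ordered stretches
  expect_false(any(d$start <= 49))
  expect_false(any(d$end >= 72))

  expect_equal(nrow(diff_annotations(ann$A, ann$A)), 0)
  expect_identical(diff_annotations(ann$A, ann$B)[c("start", "end")],
                   diff_annotations(ann$B, ann$A)[c("start", "end")])
})

test_that("annotation diffs are symmetric on randomised annotations", {
  random_annotation <- function(seed) {
    set.seed(seed)
    # two disjoint ordered cores inside residues 2..116, strands inside them
    b <- sort(sample(10:105, 4))
    ordered <- span_df(c(b[1], b[3]), c(b[2], b[4]),
                       c("core1", "core2"))
    gaps <- data.frame(
      start = c(2, b[2] + 1, b[4] + 1),
      end = c(b[1] - 1, b[3] - 1, 116)
    )
    gaps <- gaps[gaps$start <= gaps$end, ]
    disordered <- span_df(gaps$start, gaps$end, "disordered")
    s1 <- c(b[1], min(b[1] + 2, b[2]))
    strands <- span_df(s1[1], s1[2], "s1")
    structure_annotation("A", residue_span(2, 116), ordered, disordered,
                         strands)
  }
  for (seed in c(101, 202, 303, 404)) {
    a <- random_annotation(seed)
    b <- random_annotation(seed + 1)
    dab <- diff_annotations(a, b)
    dba <- diff_annotations(b, a)
    expect_identical(dab[c("start", "end")], dba[c("start", "end")])
    # differing intervals agree with a per-residue brute comparison
    differ <- vapply(2:116, function(p) {
      ra <- brute_classify(p, a)
      rb <- brute_classify(p, b)
      ra != rb
    }, logical(1))
    pos <- (2:116)[differ]
    covered <- unlist(lapply(seq_len(nrow(dab)),
                             function(i) dab$start[i]:dab$end[i]))
    expect_true(all(pos %in% covered))
  }
})

test_that("annotation container rejects invariant violations", {
  fp <- residue_span(2, 116)
  expect_error(
    structure_annotation("A", fp,
                         span_df(9, 49, "core"),
                         span_df(40, 59, "disordered"),
                         span_df(10, 14, "s")),
    "overlap"
  )
  expect_error(
    structure_annotation("A", fp,
                         span_df(9, 49, "core"),
                         span_df(50, 59, "disordered"),
                         span_df(48, 52, "s")),
    "ordered span"
  )
  expect_error(diff_annotations(ann$A, structure_annotation(
    "B", residue_span(2, 110), span_df(9, 49, "core"),
    span_df(50, 110, "disordered"), span_df(10, 14, "s"))),
    "different fibril protein spans")
})

test_that("span lists export as 1-based inclusive TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_tsv(ann$A, path)
  lines <- readLines(path)
  expect_match(lines[1], "1-based inclusive")
  df <- read.delim(path, comment.char = "#")
  expect_equal(nrow(df),
               nrow(ann$A$ordered_spans) + nrow(ann$A$disordered_spans) +
                 nrow(ann$A$strand_spans))
  expect_true(all(df$start <= df$end))
})

test_that("reported class counts are internally consistent", {
  counts <- study_reference_counts()
  expect_identical(counts$n_class_A + counts$n_class_B,
                   counts$n_selected_segments)
  expect_true(all(diff(unname(counts$fibril_counts)) < 0))
})
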