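test_that("state symbols parse to the four-state coding", {
  m <- parse_marker_matrix(c("taxon\tm1\tm2", "A\t+\t-", "B\t?\td"),
                           orientation = "taxa")
  expect_equal(as.vector(m$states["A", ]), c("+", "-"))
  expect_equal(as.vector(m$states["B", ]), c("?", "d"))
  # binary coding accepted
  b <- parse_marker_matrix(c("taxon\tm1\tm2", "A\t1\t0", "B\t?\t1"),
                           orientation = "taxa")
  expect_equal(as.vector(b$states["A", ]), c("+", "-"))
})

test_that("ragged rows and unknown symbols error with their position", {
  expect_error(parse_marker_matrix(c("taxon\tm1\tm2", "A\t+"), "taxa"),
               "row 2")
  expect_error(parse_marker_matrix(c("taxon\tm1\tm2", "A\t+\tx"), "taxa"),
               "'x'.*row 1, column 2")
})

test_that("the packaged marsupial matrix has the published shape", {
  x <- marsupial_markers()
  expect_equal(length(x$taxa), 21)
  expect_equal(length(x$markers), 53)
  expect_equal(x$outgroup, "Homo_sapiens")
  expect_true(all(x$states["Homo_sapiens", ] == "-"))
  expect_equal(sum(x$states == "d"), 1) # one deleted site, in Notoryctes
  expect_equal(unname(x$states["Notoryctes_typhlops", "168a"]), "d")
})

test_that("marker matrices round-trip through both text layouts and NEXUS coding is binary", {
  x <- marsupial_markers()
  for (orient in c("markers", "taxa")) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_marker_matrix(x, path, orientation = orient)
    back <- read_marker_matrix(path, orientation = orient,
                               outgroup = "Homo_sapiens")
    expect_identical(back$states, x$states)
    expect_identical(back$taxa, x$taxa)
  }
  nex <- withr::local_tempfile(fileext = ".nex")
  write_nexus_matrix(x, nex)
  lines <- readLines(nex)
  expect_true(any(grepl("NTAX=21 NCHAR=53", lines)))
  seqs <- sub("^\\s+\\S+\\s+", "", grep("^    ", lines, value = TRUE))
  expect_false(any(grepl("[+d]", seqs)))
  expect_true(all(grepl("^[01?]+$", seqs)))
})

test_that("support patterns reproduce the published marker counts", {
  x <- marsupial_markers()
  g <- marsupial_taxon_groups()
  expect_equal(support_pattern(x, g$australidelphia)$k, 13)
  expect_equal(support_pattern(x, g$marsupials)$k, 10)
  expect_equal(support_pattern(x, g$euaustralidelphia,
                               outside = g$marsupials[
                                 !g$marsupials %in% g$euaustralidelphia])$k, 4)
  expect_equal(support_pattern(x, c(g$paucituberculata, g$australidelphia))$k, 2)
  expect_equal(support_pattern(x, g$didelphimorphia)$k, 5)
  expect_equal(support_pattern(x, g$paucituberculata)$k, 3)
  expect_equal(support_pattern(x, g$dasyuromorphia)$k, 3)
  expect_equal(support_pattern(x, g$peramelemorphia)$k, 4)
  expect_equal(support_pattern(x, g$diprotodontia)$k, 3)
  # the published patterns are conflict-free: l = m = 0 under the edge split
  sp <- support_pattern(x, g$australidelphia,
                        split = list(g$microbiotheria, g$euaustralidelphia))
  expect_equal(c(sp$k, sp$l, sp$m), c(13, 0, 0))
})

test_that("support counting is invariant to row and column order and skips missing", {
  x <- marsupial_markers()
  g <- marsupial_taxon_groups()
  set.seed(1)
  perm <- marker_matrix(x$states[sample(x$taxa), sample(x$markers)],
                        outgroup = x$outgroup)
  expect_equal(support_pattern(perm, g$australidelphia)$k, 13)
  allmiss <- marker_matrix(matrix("?", 3, 4,
                                  dimnames = list(c("a", "b", "c"), NULL)))
  sp <- support_pattern(allmiss, c("a", "b"), split = list("a", "b"))
  expect_equal(c(sp$k, sp$l, sp$m), c(0, 0, 0))
  expect_error(support_pattern(x, character()), "non-empty")
})

test_that("conflicting alternatives are counted symmetrically", {
  st <- rbind(A = c("+", "+", "-"),
              B = c("+", "-", "+"),
              C = c("-", "+", "+"),
              O = c("-", "-", "-"))
  colnames(st) <- paste0("m", 1:3)
  x <- marker_matrix(st, outgroup = "O")
  sp <- support_pattern(x, c("A", "B"), outside = c("C", "O"),
                        split = list("A", "B"))
  expect_equal(c(sp$k, sp$l, sp$m), c(1, 1, 1))
})

test_that("the packaged matrix is free of pairwise marker conflicts", {
  expect_equal(nrow(marker_conflicts(marsupial_markers())), 0)
})
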