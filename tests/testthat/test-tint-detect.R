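test_that("a guest between continuous host fragments is one event", {
  ev <- detect_nested_insertions(nested_annotation())
  expect_equal(nrow(ev), 1)
  expect_equal(ev$guest_family, "WSINE1")
  expect_equal(ev$host_family, "MIR3")
  expect_equal(ev$continuity_gap, 0L)
})

test_that("continuity, fragment-length, strand and ambiguity rules are enforced", {
  # consensus gap 149 bp >> window
  broken <- nested_annotation(host_cons = list(c(1, 200), c(350, 550)))
  expect_equal(nrow(detect_nested_insertions(broken, continuity_window = 30)), 0)
  # host fragments on different strands never pair
  ann <- nested_annotation()
  ann$strand[3] <- "-"
  expect_equal(nrow(detect_nested_insertions(ann)), 0)
  # short host fragment fails min_fragment
  ev <- detect_nested_insertions(nested_annotation(), min_fragment = 250)
  expect_equal(nrow(ev), 0)
  # two guests between the same host fragments: ambiguous, no event
  two <- repeat_annotation(tibble::tibble(
    sequence_id = "seq1",
    genome_start = c(1000, 1250, 1310, 1500),
    genome_end = c(1199, 1300, 1450, 1699),
    strand = "+",
    family = c("MIR3", "WSINE1", "WSINE1", "MIR3"),
    repeat_class = "SINE",
    consensus_start = c(1, 1, 1, 201),
    consensus_end = c(200, 51, 141, 400)), "toy")
  expect_equal(nrow(detect_nested_insertions(two)), 0)
})

test_that("minus-strand hosts and self-nesting are detected", {
  minus <- nested_annotation(host_cons = list(c(201, 400), c(1, 200)),
                             strand = "-")
  ev <- detect_nested_insertions(minus)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$continuity_gap, 0L)
  selfn <- nested_annotation(guest_family = "MIR3")
  ev2 <- detect_nested_insertions(selfn)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$guest_family, ev2$host_family)
})

test_that("detector reproduces the simulator's clean-event ledger exactly", {
  ds <- simulate_retroposons(toy_sim_config(seed = 41))
  for (tip in names(ds$annotations)) {
    ann <- ds$annotations[[tip]]
    ev <- detect_nested_insertions(ann, continuity_window = 30,
                                   min_fragment = 30)
    truth <- ds$tint_truth[ds$tint_truth$tip == tip & ds$tint_truth$clean, ]
    detected_guests <- ann$rm_id[match(ev$guest_hit_id, ann$hit_id)]
    expect_setequal(detected_guests, as.character(truth$guest_id))
    # families agree event by event
    got <- ev[order(as.integer(detected_guests)), ]
    want <- truth[order(truth$guest_id), ]
    expect_equal(got$guest_family, want$guest_family)
    expect_equal(got$host_family, want$host_family)
  }
})

test_that("TinT count matrices tally events and validate family lists", {
  empty <- build_tint_matrix(tibble::tibble(guest_family = character(),
                                            host_family = character()),
                             families = c("A", "B"))
  expect_true(all(empty == 0))
  expect_equal(attr(empty, "total_events"), 0L)

  ev <- tibble::tibble(guest_family = c("A", "A", "B"),
                       host_family = c("B", "B", "A"))
  m <- build_tint_matrix(ev, families = c("A", "B"))
  expect_equal(m["A", "B"], 2L)
  expect_equal(m["B", "A"], 1L)
  expect_equal(sum(m), 3L)
  expect_error(build_tint_matrix(ev, families = "A"), "B")

  ds <- simulate_retroposons(toy_sim_config(seed = 42))
  ann <- ds$annotations[["B"]]
  ev <- detect_nested_insertions(ann)
  m <- build_tint_matrix(ev)
  truth <- ds$tint_truth[ds$tint_truth$tip == "B" & ds$tint_truth$clean, ]
  m_truth <- build_tint_matrix(
    tibble::tibble(guest_family = truth$guest_family,
                   host_family = truth$host_family),
    families = rownames(m))
  expect_equal(unclass(m), unclass(m_truth))

  # write / read round-trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tint_matrix(m, path)
  expect_equal(unclass(read_tint_matrix(path)), unclass(m))
})
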