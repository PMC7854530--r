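test_that("bipartite construction keeps isolated facilities and skips unknown ones", {
  fac <- tibble::tibble(provider_id = c("A", "B", "C"))
  ties <- tibble::tibble(provider_id = c("A", "B"), owner_key = "O LLC",
                         owner_kind = "organization")
  g <- build_bipartite(ties, fac, hrr = "HRR001", date = 1)
  expect_equal(sum(!igraph::V(g)$type), 3)   # facilities
  expect_equal(sum(igraph::V(g)$type), 1)    # owners
  expect_equal(igraph::ecount(g), 2)
  expect_equal(igraph::degree(g)[["C"]], 0)

  ties_bad <- dplyr::add_row(ties, provider_id = "Z", owner_key = "O LLC",
                             owner_kind = "organization")
  expect_warning(g2 <- build_bipartite(ties_bad, fac), "absent from the HRR")
  expect_equal(igraph::ecount(g2), 2)
})

test_that("projection weight equals the number of shared owners", {
  fac <- tibble::tibble(provider_id = c("A", "B", "C"))
  ties <- tibble::tibble(
    provider_id = c("A", "B", "A", "B", "A", "B", "C"),
    owner_key = c("O1", "O1", "O2", "O2", "SOLE A", "SOLE B", "SOLE C"),
    owner_kind = "organization")
  p <- project_facilities(build_bipartite(ties, fac))
  e <- projection_edges(p)
  expect_equal(e, tibble::tibble(a = "A", b = "B", weight = 2L))

  # a star owner induces a unit-weight triangle
  star <- tibble::tibble(provider_id = c("A", "B", "C"), owner_key = "O",
                         owner_kind = "organization")
  ps <- project_facilities(build_bipartite(star, fac))
  es <- projection_edges(ps)
  expect_equal(nrow(es), 3)
  expect_true(all(es$weight == 1))
})

test_that("projection matches the brute-force pairwise oracle on random graphs", {
  set.seed(202)
  for (rep in 1:40) {
    rb <- random_bipartite_ties(sample(2:12, 1), sample(1:8, 1), runif(1, 0.1, 0.5))
    p <- project_facilities(build_bipartite(rb$ties, rb$facilities))
    expect_equal(projection_edges(p),
                 brute_force_projection(rb$ties, rb$facilities$provider_id))
    # degree >= 1 iff some owner is shared (projection-level invariant)
    aff <- classify_affiliation(p)
    oracle <- brute_force_projection(rb$ties, rb$facilities$provider_id)
    linked <- unique(c(oracle$a, oracle$b))
    expect_setequal(aff$provider_id[aff$class == "multiple"], linked)
  }
})

test_that("affiliation classes follow the degree rule", {
  fx <- fig2_fixture()
  p <- project_facilities(build_bipartite(fx$ties, fx$facilities, hrr = "HRR001", date = 5))
  aff <- classify_affiliation(p)
  expect_equal(sum(aff$class == "multiple"), fx$n_multiple)
  expect_equal(sum(aff$class == "single"), fx$n_single)
  # a node in the size-5 clique has degree 4
  expect_equal(aff$degree[aff$provider_id == "F01"], 4L)
  expect_equal(aff$degree[aff$provider_id == "F14"], 0L)
  expect_true(all((aff$degree >= 1) == (aff$class == "multiple")))
})

test_that("Louvain groups recover planted communities and exclude singletons", {
  # two disjoint dyads -> two groups of size 2
  fac <- tibble::tibble(provider_id = sprintf("F%d", 1:5))
  ties <- tibble::tibble(
    provider_id = c("F1", "F2", "F3", "F4"),
    owner_key = c("O1", "O1", "O2", "O2"), owner_kind = "organization")
  p <- project_facilities(build_bipartite(ties, fac))
  grp <- detect_ownership_groups(p)
  expect_equal(nrow(grp), 4)
  expect_equal(sort(unique(grp$group_size)), 2L)
  expect_equal(length(unique(grp$group_id)), 2)
  expect_false("F5" %in% grp$provider_id)

  # a 5-clique is one group of size 5
  clique <- tibble::tibble(provider_id = sprintf("C%d", 1:5), owner_key = "O",
                           owner_kind = "organization")
  pc <- project_facilities(build_bipartite(clique, tibble::tibble(provider_id = sprintf("C%d", 1:5))))
  gc <- detect_ownership_groups(pc)
  expect_equal(unique(gc$group_size), 5L)
  expect_equal(length(unique(gc$group_id)), 1)

  # empty projection -> empty group table
  iso <- build_bipartite(ties[0, ], fac)
  expect_equal(nrow(detect_ownership_groups(project_facilities(iso))), 0)
})

test_that("groups partition exactly the multiple-affiliation node set", {
  set.seed(303)
  for (rep in 1:25) {
    rb <- random_bipartite_ties(sample(4:12, 1), sample(2:8, 1), runif(1, 0.15, 0.5))
    p <- project_facilities(build_bipartite(rb$ties, rb$facilities))
    aff <- classify_affiliation(p)
    grp <- detect_ownership_groups(p)
    expect_setequal(grp$provider_id, aff$provider_id[aff$class == "multiple"])
    expect_equal(anyDuplicated(grp$provider_id), 0)
    if (nrow(grp)) {
      sizes <- dplyr::distinct(grp, group_id, group_size)
      expect_equal(sum(sizes$group_size), sum(aff$class == "multiple"))
      expect_true(all(sizes$group_size >= 2))
    }
  }
})

test_that("Louvain modularity is at least the connected-components partition's", {
  set.seed(404)
  for (rep in 1:20) {
    rb <- random_bipartite_ties(10, 6, 0.3)
    p <- project_facilities(build_bipartite(rb$ties, rb$facilities))
    if (igraph::ecount(p) == 0) next
    grp <- detect_ownership_groups(p)
    memb <- rep(NA_integer_, igraph::vcount(p))
    names(memb) <- igraph::V(p)$name
    memb[grp$provider_id] <- grp$group_id
    memb[is.na(memb)] <- max(grp$group_id, 0) + seq_len(sum(is.na(memb)))
    comp <- igraph::components(p)$membership
    m_louvain <- igraph::modularity(p, memb, weights = igraph::E(p)$weight)
    m_comp <- igraph::modularity(p, comp, weights = igraph::E(p)$weight)
    expect_gte(m_louvain, m_comp - 1e-12)
  }
})

test_that("classification is invariant to input row order", {
  set.seed(505)
  rb <- random_bipartite_ties(10, 6, 0.3)
  p1 <- project_facilities(build_bipartite(rb$ties, rb$facilities))
  shuffled <- rb$ties[sample(nrow(rb$ties)), ]
  p2 <- project_facilities(build_bipartite(shuffled, rb$facilities[sample(nrow(rb$facilities)), ]))
  expect_equal(classify_affiliation(p1), classify_affiliation(p2))
  expect_equal(detect_ownership_groups(p1), detect_ownership_groups(p2))
})

test_that("co-owning organization count matches hand counts and planted truth", {
  # dyad sharing O, each also solely owned by P and Q -> 3 organizations
  fac <- tibble::tibble(provider_id = c("A", "B"))
  ties <- tibble::tibble(provider_id = c("A", "B", "A", "B"),
                         owner_key = c("O", "O", "P", "Q"),
                         owner_kind = "organization")
  g <- build_bipartite(ties, fac)
  grp <- detect_ownership_groups(project_facilities(g))
  expect_equal(count_coowning_organizations(g, grp), 3L)

  # no groups -> 0
  solo <- tibble::tibble(provider_id = c("A", "B"), owner_key = c("P", "Q"),
                         owner_kind = "organization")
  g0 <- build_bipartite(solo, fac)
  expect_equal(count_coowning_organizations(
    g0, detect_ownership_groups(project_facilities(g0))), 0L)

  # generator bookkeeping: every planted shared owner plus the group's
  # members' sole/secondary owners are incident to grouped facilities
  sim <- simulate_nhc(tiny_sim_config(n_facilities = 80, n_hrrs = 2,
                                      pct_individual_owners = 0,
                                      second_owner_rate = 0), seed = 61)
  panel <- sim_panel(sim)
  net <- derive_networks(panel)
  truth <- sim$truth$facilities
  for (h in unique(truth$hrr)) {
    grouped <- truth$provider_id[truth$hrr == h & truth$affiliation == "multiple"]
    n_shared <- length(unique(truth$group_id[truth$hrr == h &
                                               !is.na(truth$group_id)]))
    fac_h <- panel$snapshots[panel$snapshots$hrr == h & panel$snapshots$date == 1, ]
    own_h <- panel$owners[panel$owners$date == 1 &
                            panel$owners$provider_id %in% fac_h$provider_id, ]
    g <- build_bipartite(filter_registered_organizations(own_h, quiet = TRUE), fac_h,
                         hrr = h, date = 1)
    grp <- detect_ownership_groups(project_facilities(g))
    # planted: one shared owner per group + one sole owner per member
    expect_equal(count_coowning_organizations(g, grp),
                 n_shared + length(grouped))
  }
})

test_that("GraphML export round-trips node levels and edge weights", {
  fx <- fig2_fixture()
  g <- build_bipartite(fx$ties, fx$facilities)
  p <- project_facilities(g)
  path <- tempfile(fileext = ".graphml")
  export_graphml(p, path)
  back <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(p))
  expect_equal(sort(igraph::E(back)$weight), sort(igraph::E(p)$weight))
})
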