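#' Build the two-mode facility-owner graph for one HRR and date
#'
#' Nodes are facilities (Federal Provider Numbers) and
#' registered-organization owner keys; an edge records that the owner holds
#' the facility. Facilities with no organization owner in the HRR are kept
#' as isolated nodes, so the downstream projection can classify them as
#' single-affiliation. Owner records referencing a facility absent from the
#' HRR snapshot are skipped with a warning.
#'
#' Vertices are inserted in sorted name order so that all downstream
#' results are invariant to the row order of the input tables.
#'
#' @param owners Owner-record tibble already restricted to
#'   organization-kind owners (see [filter_registered_organizations()])
#'   with normalized `owner_key`s.
#' @param facilities Snapshot tibble restricted to one HRR and date.
#' @param hrr,date Identifiers stored as graph attributes.
#' @return An undirected bipartite [igraph][igraph::igraph-package] graph;
#'   vertex attribute `type` is `FALSE` for facilities and `TRUE` for
#'   owners, `level` is `"facility"`/`"owner"`.
#' @export
build_bipartite <- function(owners, facilities, hrr = NA, date = NA) {
  fac_ids <- sort(unique(facilities$provider_id))
  ties <- owners |>
    dplyr::filter(.data$owner_kind == "organization") |>
    dplyr::distinct(.data$provider_id, .data$owner_key)
  unknown <- setdiff(ties$provider_id, fac_ids)
  if (length(unknown)) {
    warning(length(unknown), " owner record(s) reference facilities absent from the HRR snapshot; skipped",
            call. = FALSE)
    ties <- ties[ties$provider_id %in% fac_ids, ]
  }
  owner_ids <- sort(unique(ties$owner_key))
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(fac_ids), name = fac_ids,
                            type = FALSE, level = "facility")
  g <- igraph::add_vertices(g, length(owner_ids), name = owner_ids,
                            type = TRUE, level = "owner")
  if (nrow(ties)) {
    ties <- dplyr::arrange(ties, .data$provider_id, .data$owner_key)
    g <- igraph::add_edges(g, rbind(match(ties$provider_id, igraph::V(g)$name),
                                    match(ties$owner_key, igraph::V(g)$name)))
  }
  g <- igraph::set_graph_attr(g, "hrr", hrr)
  igraph::set_graph_attr(g, "date", date)
}

#' Project the bipartite graph onto facilities
#'
#' One-mode weighted graph over facilities; the weight of edge (a, b) is
#' the number of distinct owner keys the two facilities share. Isolated
#' facilities are retained.
#'
#' @param g Bipartite graph from [build_bipartite()].
#' @return Undirected weighted igraph over the facility nodes.
#' @export
project_facilities <- function(g) {
  stopifnot(igraph::is_bipartite(g))
  p <- igraph::bipartite_projection(g, multiplicity = TRUE, which = "false")
  p <- igraph::set_graph_attr(p, "hrr", igraph::graph_attr(g, "hrr"))
  igraph::set_graph_attr(p, "date", igraph::graph_attr(g, "date"))
}

#' Classify facilities as single or multiple affiliation
#'
#' A facility has multiple affiliation (is part of a super-organization)
#' iff it shares at least one registered-organization owner with another
#' facility in its HRR, i.e. iff its degree in the facility projection is
#' at least one. Degree here is unweighted: the number of *other*
#' facilities tied to, regardless of how many owners are shared.
#'
#' @param p Facility projection from [project_facilities()].
#' @return Tibble with `provider_id`, `degree`, `class`
#'   (`"single"`/`"multiple"`), `hrr`, `date`.
#' @export
classify_affiliation <- function(p) {
  deg <- igraph::degree(p)
  tibble::tibble(
    provider_id = igraph::V(p)$name,
    degree = as.integer(deg),
    class = ifelse(deg >= 1, "multiple", "single"),
    hrr = igraph::graph_attr(p, "hrr"),
    date = igraph::graph_attr(p, "date")
  )
}

#' Detect ownership groups by Louvain community detection
#'
#' Runs the Louvain modularity algorithm on the weighted facility
#' projection (shared-owner counts as edge weights) and reports the
#' communities of size two or more as ownership groups. Single-affiliation
#' facilities are singleton communities by construction and are excluded
#' from groups; in the rare event the modularity search isolates a
#' connected node, it is merged into its heaviest neighbour's community so
#' that groups always partition exactly the multiple-affiliation set.
#'
#' The community search shuffles node processing order internally; runs are
#' reproducible because the RNG is seeded (and input order is already
#' canonicalized by [build_bipartite()]).
#'
#' @param p Facility projection.
#' @param resolution Modularity resolution parameter (1 = classic
#'   modularity).
#' @param seed RNG seed for the community search.
#' @return Tibble with one row per grouped facility: `provider_id`,
#'   `group_id`, `group_size`, `hrr`, `date`. Zero rows when the
#'   projection has no edges.
#' @export
detect_ownership_groups <- function(p, resolution = 1, seed = 20160301) {
  if (igraph::ecount(p) == 0) {
    return(tibble::tibble(provider_id = character(), group_id = integer(),
                          group_size = integer(),
                          hrr = igraph::graph_attr(p, "hrr"),
                          date = igraph::graph_attr(p, "date"))[0, ])
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(p, weights = igraph::E(p)$weight,
                                resolution = resolution)
  memb <- igraph::membership(cl)
  deg <- igraph::degree(p)

  # guard: a connected node must not sit in a singleton community
  sizes <- table(memb)
  lone <- names(deg)[deg >= 1 & sizes[as.character(memb)] == 1]
  for (v in lone) {
    inc <- igraph::incident(p, v)
    nb <- setdiff(igraph::ends(p, inc, names = TRUE), v)
    best <- nb[which.max(igraph::E(p)$weight[inc])[1]]
    memb[v] <- memb[best]
    sizes <- table(memb)
  }

  out <- tibble::tibble(provider_id = igraph::V(p)$name,
                        group_id = as.integer(memb),
                        degree = as.integer(deg)) |>
    dplyr::filter(.data$degree >= 1) |>
    dplyr::mutate(group_size = dplyr::n(), .by = "group_id") |>
    dplyr::filter(.data$group_size >= 2)
  # renumber groups 1..k in order of smallest member id for stable output
  first <- out |>
    dplyr::summarise(lead = min(.data$provider_id), .by = "group_id") |>
    dplyr::arrange(.data$lead)
  out |>
    dplyr::mutate(group_id = match(.data$group_id, first$group_id),
                  hrr = igraph::graph_attr(p, "hrr"),
                  date = igraph::graph_attr(p, "date")) |>
    dplyr::select("provider_id", "group_id", "group_size", "hrr", "date") |>
    dplyr::arrange(.data$group_id, .data$provider_id)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Count registered organizations with shared ownership
#'
#' Number of distinct owner keys incident (in the bipartite graph) to at
#' least one facility that is a member of an ownership group — the
#' organizations participating in super-organization.
#'
#' @param g Bipartite graph.
#' @param groups Tibble from [detect_ownership_groups()].
#' @return Integer count.
#' @export
count_coowning_organizations <- function(g, groups) {
  if (nrow(groups) == 0) return(0L)
  fac <- intersect(groups$provider_id, igraph::V(g)$name)
  if (!length(fac)) return(0L)
  nb <- igraph::adjacent_vertices(g, fac)
  length(unique(unlist(lapply(nb, function(v) v$name))))
}

#' Export a graph to GraphML
#'
#' Nodes carry a `level` attribute (`facility`/`owner`) on bipartite
#' graphs; projection edges carry their shared-owner `weight`.
#'
#' @param g An igraph graph.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
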