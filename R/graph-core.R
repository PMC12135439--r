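#' Directed graph over a fixed gene set
#'
#' Light container for a directed graph on `n_nodes` genes, stored as a 0/1
#' adjacency matrix with `adj[i, j] == 1` meaning a regulatory edge
#' `i -> j`.  Used both for candidate causal structures (DAGs) and for
#' cyclic reference networks before DAG repair.
#'
#' @param n_nodes Number of genes (positive integer).
#' @param edges Edges as a two-column matrix or data frame of
#'   `(from, to)` indices (1-based), or `NULL` for the empty graph.
#' @param labels Optional character vector of unique gene names, length
#'   `n_nodes`.
#'
#' @return An object of class `grn_dag`: a list with elements `n_nodes`,
#'   `adj` (integer matrix) and `labels`.
#' @examples
#' g <- dag(3, rbind(c(1, 2), c(2, 3)))
#' is_acyclic(g)
#' @export
dag <- function(n_nodes, edges = NULL, labels = NULL) {
  stopifnot(is.numeric(n_nodes), length(n_nodes) == 1, n_nodes >= 1)
  n <- as.integer(n_nodes)
  adj <- matrix(0L, n, n)
  if (!is.null(edges) && NROW(edges) > 0) {
    e <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(e) <- "integer"
    if (any(e < 1L | e > n)) stop("edge indices out of range [1, n_nodes]")
    if (any(e[, 1] == e[, 2])) stop("self-loops are not allowed")
    adj[e] <- 1L
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) stop("labels must have length n_nodes")
    if (anyDuplicated(labels)) stop("labels must be unique")
    dimnames(adj) <- list(labels, labels)
  }
  structure(list(n_nodes = n, adj = adj, labels = labels), class = "grn_dag")
}

#' @export
print.grn_dag <- function(x, ...) {
  cat(sprintf("<grn_dag> %d genes, %d edges%s\n", x$n_nodes, sum(x$adj),
              if (is_acyclic(x)) " (acyclic)" else " (cyclic)"))
  invisible(x)
}

#' Partially directed graph (essential graph / CPDAG)
#'
#' Represents a Markov equivalence class: compelled edges are directed,
#' reversible edges undirected.  A gene pair may appear in at most one of
#' the two edge sets, and never directed in both orientations.
#'
#' @param n_nodes Number of genes.
#' @param directed Two-column matrix of directed edges `(from, to)`, or
#'   `NULL`.
#' @param undirected Two-column matrix of undirected pairs (order
#'   irrelevant), or `NULL`.
#' @param labels Optional unique gene names.
#'
#' @return An object of class `grn_pdag` with 0/1 matrices `dir` (directed
#'   part) and `undir` (symmetric undirected part).
#' @export
pdag <- function(n_nodes, directed = NULL, undirected = NULL, labels = NULL) {
  n <- as.integer(n_nodes)
  d <- matrix(0L, n, n)
  u <- matrix(0L, n, n)
  fill <- function(m, edges, sym) {
    if (is.null(edges) || NROW(edges) == 0) return(m)
    e <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(e) <- "integer"
    if (any(e < 1L | e > n)) stop("edge indices out of range")
    if (any(e[, 1] == e[, 2])) stop("self-loops are not allowed")
    m[e] <- 1L
    if (sym) m[e[, 2:1, drop = FALSE]] <- 1L
    m
  }
  d <- fill(d, directed, sym = FALSE)
  u <- fill(u, undirected, sym = TRUE)
  if (any(d & t(d))) stop("a pair may not be directed in both orientations")
  if (any(u & (d | t(d)))) stop("a pair may not be both directed and undirected")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n || anyDuplicated(labels)) stop("labels must be unique, length n_nodes")
    dimnames(d) <- dimnames(u) <- list(labels, labels)
  }
  structure(list(n_nodes = n, dir = d, undir = u, labels = labels),
            class = "grn_pdag")
}

#' @export
print.grn_pdag <- function(x, ...) {
  cat(sprintf("<grn_pdag> %d genes, %d directed, %d undirected edges\n",
              x$n_nodes, sum(x$dir), sum(x$undir) / 2L))
  invisible(x)
}

pdag_from_matrices <- function(d, u, labels = NULL) {
  structure(list(n_nodes = nrow(d), dir = d, undir = u, labels = labels),
            class = "grn_pdag")
}

dag_from_adj <- function(adj, labels = NULL) {
  storage.mode(adj) <- "integer"
  if (!is.null(labels)) dimnames(adj) <- list(labels, labels)
  structure(list(n_nodes = nrow(adj), adj = adj, labels = labels),
            class = "grn_dag")
}

#' Extract the edge list of a graph
#'
#' @param g A `grn_dag` or `grn_pdag`.
#' @return A tibble with columns `from`, `to` and (for PDAGs) `type`
#'   (`"directed"` or `"undirected"`, the latter listed once with
#'   `from < to`).
#' @export
edges <- function(g) {
  if (inherits(g, "grn_dag")) {
    idx <- which(g$adj == 1L, arr.ind = TRUE)
    return(tibble::tibble(from = as.integer(idx[, 1]), to = as.integer(idx[, 2])))
  }
  stopifnot(inherits(g, "grn_pdag"))
  d <- which(g$dir == 1L, arr.ind = TRUE)
  u <- which(g$undir == 1L & upper.tri(g$undir), arr.ind = TRUE)
  dplyr::bind_rows(
    tibble::tibble(from = as.integer(d[, 1]), to = as.integer(d[, 2]),
                   type = rep("directed", nrow(d))),
    tibble::tibble(from = as.integer(u[, 1]), to = as.integer(u[, 2]),
                   type = rep("undirected", nrow(u)))
  )
}

#' Count the edges of a graph
#'
#' @param g A `grn_dag` or `grn_pdag`.
#' @return Number of edges (an undirected PDAG edge counts once).
#' @export
n_edges <- function(g) {
  if (inherits(g, "grn_dag")) sum(g$adj) else sum(g$dir) + sum(g$undir) / 2L
}

#' Test whether a directed graph is acyclic
#'
#' Kahn's algorithm: repeatedly strip zero-in-degree nodes; the graph is a
#' DAG iff every node gets stripped.
#'
#' @param g A `grn_dag` (or a plain 0/1 adjacency matrix).
#' @return `TRUE` iff `g` contains no directed cycle.
#' @export
is_acyclic <- function(g) {
  adj <- if (inherits(g, "grn_dag")) g$adj else g
  !is.null(topological_order(adj))
}

# Deterministic topological order (smallest index first); NULL if cyclic.
topological_order <- function(adj) {
  n <- nrow(adj)
  indeg <- colSums(adj)
  alive <- rep(TRUE, n)
  out <- integer(0)
  repeat {
    ready <- which(alive & indeg == 0)
    if (length(ready) == 0) break
    v <- ready[1]
    out <- c(out, v)
    alive[v] <- FALSE
    indeg <- indeg - adj[v, ]  # children of v lose one in-edge
    indeg[!alive] <- 0
  }
  if (length(out) < n) NULL else out
}

# Is there a directed path from `from` to `to`?  (BFS on the adjacency.)
has_path <- function(adj, from, to) {
  if (from == to) return(TRUE)
  n <- nrow(adj)
  seen <- logical(n)
  frontier <- from
  seen[from] <- TRUE
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    if (any(nxt == to)) return(TRUE)
    if (!length(nxt)) return(FALSE)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  FALSE
}

#' Complete a partially directed graph under Meek's rules
#'
#' Applies the four orientation-propagation rules R1-R4 until no rule
#' fires.  The rules direct an undirected edge whenever one orientation
#' would necessarily create a new v-structure or a directed cycle in every
#' consistent DAG extension:
#' \itemize{
#'   \item R1: `a -> b`, `b - c`, `a`/`c` nonadjacent  =>  `b -> c`;
#'   \item R2: `a -> c -> b`, `a - b`  =>  `a -> b`;
#'   \item R3: `a - b`, `a - c`, `a - d`, `c -> b`, `d -> b`, `c`/`d`
#'     nonadjacent  =>  `a -> b`;
#'   \item R4: `a - b`, `a - c`, `c -> d -> b`, `b`/`c` nonadjacent
#'     =>  `a -> b`.
#' }
#' The skeleton is preserved, directed edges are never removed, and the
#' operation is idempotent.
#'
#' @param p A `grn_pdag` whose directed part is acyclic.
#' @return The completed `grn_pdag`.
#' @export
meek_closure <- function(p) {
  stopifnot(inherits(p, "grn_pdag"))
  if (!is_acyclic(p$dir)) stop("directed part of the PDAG is cyclic")
  d <- p$dir
  u <- p$undir
  n <- p$n_nodes
  repeat {
    adj <- (d | t(d) | u) * 1L
    changed <- FALSE
    pairs <- which(u == 1L, arr.ind = TRUE)  # both orders (a, b)
    for (k in seq_len(nrow(pairs))) {
      a <- pairs[k, 1]; b <- pairs[k, 2]
      if (u[a, b] == 0L) next  # oriented earlier in this sweep
      orient <- FALSE
      # R1: some parent of a nonadjacent to b  =>  a -> b
      pa <- which(d[, a] == 1L)
      if (length(pa) && any(adj[pa, b] == 0L & pa != b)) orient <- TRUE
      # R2: directed path a -> x -> b
      if (!orient && any(d[a, ] == 1L & d[, b] == 1L)) orient <- TRUE
      if (!orient) {
        # R3: two nonadjacent c, d with a - c, a - d, c -> b, d -> b
        cand <- which(u[a, ] == 1L & d[, b] == 1L)
        if (length(cand) >= 2) {
          sub <- adj[cand, cand, drop = FALSE]
          if (any(sub[upper.tri(sub)] == 0L)) orient <- TRUE
        }
        # R4: a - c, c -> x -> b with b, c nonadjacent
        if (!orient) {
          cand <- which(u[a, ] == 1L & adj[, b] == 0L)
          cand <- cand[cand != b]
          for (cc in cand) {
            if (any(d[cc, ] == 1L & d[, b] == 1L)) { orient <- TRUE; break }
          }
        }
      }
      # On a well-formed essential graph a compelled orientation can never
      # close a directed cycle; on arbitrary PDAG input it can, in which
      # case the edge is left undirected (keeps the closure total,
      # cycle-free and idempotent).
      if (orient && !has_path(d, b, a)) {
        d[a, b] <- 1L
        u[a, b] <- u[b, a] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pdag_from_matrices(d, u, p$labels)
}

#' Essential graph (CPDAG) of a DAG
#'
#' Converts a DAG to the essential graph of its Markov equivalence class:
#' the skeleton is kept, edges taking part in a v-structure (collider with
#' nonadjacent parents) are directed, the Meek closure propagates all
#' further compelled orientations, and every remaining edge is undirected
#' (reversible within the class).
#'
#' @param g An acyclic `grn_dag`.
#' @return A `grn_pdag`.
#' @examples
#' cpdag(dag(3, rbind(c(1, 2), c(2, 3))))  # chain: fully undirected
#' @export
cpdag <- function(g) {
  stopifnot(inherits(g, "grn_dag"))
  if (!is_acyclic(g)) stop("input graph must be acyclic")
  adj <- g$adj
  n <- g$n_nodes
  skel <- (adj | t(adj)) * 1L
  d <- matrix(0L, n, n)
  # orient v-structures a -> c <- b with a, b nonadjacent
  for (cc in seq_len(n)) {
    pa <- which(adj[, cc] == 1L)
    if (length(pa) >= 2) {
      for (i in seq_along(pa)) for (j in seq_along(pa)) {
        if (i < j && skel[pa[i], pa[j]] == 0L) {
          d[pa[i], cc] <- 1L
          d[pa[j], cc] <- 1L
        }
      }
    }
  }
  u <- skel
  u[d == 1L | t(d) == 1L] <- 0L
  out <- meek_closure(pdag_from_matrices(d, u, g$labels))
  # Meek closure of a DAG's v-structure core only ever orients edges the
  # DAG itself orients; keep orientation consistent as a safety net.
  out
}

#' Repair a cyclic reference network to a DAG
#'
#' Gene-network gold standards often contain feedback (in particular
#' reciprocal regulation), so they are not DAGs.  This operation removes a
#' small, deterministic set of edges to obtain one:
#' \enumerate{
#'   \item every reciprocal pair (2-cycle) is resolved by dropping the
#'     member that runs backwards in a deterministic topological order of
#'     the graph with all reciprocal pairs removed (falling back to step 2
#'     when that reduced graph is itself cyclic);
#'   \item while directed cycles remain, the lexicographically smallest
#'     edge of the first cycle found by a depth-first search is removed.
#' }
#' Already-acyclic input is returned unchanged with an empty removal set.
#'
#' @param g A `grn_dag`, possibly cyclic.
#' @return A list with elements `dag` (acyclic `grn_dag`) and `removed`
#'   (tibble of removed edges `from`, `to`).
#' @export
repair_to_dag <- function(g) {
  stopifnot(inherits(g, "grn_dag"))
  adj <- g$adj
  removed <- NULL
  recip <- which(adj == 1L & t(adj) == 1L & upper.tri(adj), arr.ind = TRUE)
  if (nrow(recip) > 0) {
    reduced <- adj
    for (k in seq_len(nrow(recip))) {
      i <- recip[k, 1]; j <- recip[k, 2]
      reduced[i, j] <- reduced[j, i] <- 0L
    }
    ord <- topological_order(reduced)
    if (!is.null(ord)) {
      pos <- order(ord)  # pos[v] = rank of v in the order
      for (k in seq_len(nrow(recip))) {
        i <- recip[k, 1]; j <- recip[k, 2]
        drop_edge <- if (pos[i] < pos[j]) c(j, i) else c(i, j)
        adj[drop_edge[1], drop_edge[2]] <- 0L
        removed <- rbind(removed, drop_edge)
      }
    }
  }
  # generic cycle breaking for whatever is left
  repeat {
    cyc <- find_cycle(adj)
    if (is.null(cyc)) break
    e <- cyc[order(cyc[, 1], cyc[, 2]), , drop = FALSE][1, ]
    adj[e[1], e[2]] <- 0L
    removed <- rbind(removed, e)
  }
  removed <- if (is.null(removed)) {
    tibble::tibble(from = integer(0), to = integer(0))
  } else {
    tibble::tibble(from = as.integer(removed[, 1]), to = as.integer(removed[, 2]))
  }
  list(dag = dag_from_adj(adj, g$labels), removed = removed)
}

# First directed cycle found by DFS from the smallest node, as an edge
# matrix (rows (from, to)); NULL if acyclic.
find_cycle <- function(adj) {
  n <- nrow(adj)
  color <- integer(n)  # 0 white, 1 on stack, 2 done
  parent_edge <- vector("list", n)
  for (s in seq_len(n)) {
    if (color[s] != 0L) next
    stack <- list(list(v = s, kids = which(adj[s, ] == 1L), k = 0L))
    color[s] <- 1L
    while (length(stack)) {
      top <- stack[[length(stack)]]
      if (top$k < length(top$kids)) {
        top$k <- top$k + 1L
        stack[[length(stack)]] <- top
        w <- top$kids[top$k]
        if (color[w] == 1L) {
          # found cycle: walk stack from w to top
          vs <- vapply(stack, function(f) f$v, integer(1))
          start <- match(w, vs)
          path <- vs[start:length(vs)]
          cyc <- cbind(path, c(path[-1], w))
          return(unname(cyc))
        } else if (color[w] == 0L) {
          color[w] <- 1L
          stack[[length(stack) + 1L]] <- list(v = w, kids = which(adj[w, ] == 1L), k = 0L)
        }
      } else {
        color[top$v] <- 2L
        stack[[length(stack)]] <- NULL
      }
    }
  }
  NULL
}

# Per-unordered-pair state codes for a directed graph:
# 0 none, 1 i->j, 2 j->i, 3 both (i < j).
pair_states_directed <- function(adj) {
  up <- upper.tri(adj)
  adj[up] + 2L * t(adj)[up]
}

# State codes for a PDAG: 0 none, 1 i->j, 2 j->i, 3 undirected (i < j).
pair_states_pdag <- function(p) {
  up <- upper.tri(p$dir)
  p$dir[up] + 2L * t(p$dir)[up] + 3L * p$undir[up]
}

#' Structural Hamming distance between two networks
#'
#' Counts, over unordered gene pairs, how many pairs disagree between the
#' two graphs.
#' \describe{
#'   \item{`directed`}{pairs whose edge presence or orientation differs;
#'     a reversed edge counts `reversal_cost` (default 1).}
#'   \item{`undirected`}{Hamming distance between the two skeletons.}
#'   \item{`pdag`}{pairs whose state in \{forward, reverse, undirected,
#'     absent\} differs (inputs must be `grn_pdag`).}
#' }
#'
#' @param a,b Graphs over the same gene set: `grn_dag` for modes
#'   `directed`/`undirected`, `grn_pdag` for mode `pdag`.
#' @param mode One of `"directed"`, `"undirected"`, `"pdag"`.
#' @param reversal_cost Cost of a reversed edge in `directed` mode; the
#'   common edge-operation convention is 1, set 2 to count both wrong
#'   adjacency-matrix entries.
#' @return Non-negative number.
#' @export
shd <- function(a, b, mode = c("directed", "undirected", "pdag"),
                reversal_cost = 1) {
  mode <- match.arg(mode)
  if (mode == "pdag") {
    stopifnot(inherits(a, "grn_pdag"), inherits(b, "grn_pdag"))
    if (a$n_nodes != b$n_nodes) stop("graphs must share the node set")
    return(sum(pair_states_pdag(a) != pair_states_pdag(b)))
  }
  stopifnot(inherits(a, "grn_dag"), inherits(b, "grn_dag"))
  if (a$n_nodes != b$n_nodes) stop("graphs must share the node set")
  if (mode == "undirected") {
    sa <- (a$adj | t(a$adj))
    sb <- (b$adj | t(b$adj))
    return(sum(sa[upper.tri(sa)] != sb[upper.tri(sb)]))
  }
  sa <- pair_states_directed(a$adj)
  sb <- pair_states_directed(b$adj)
  diff <- sa != sb
  reversed <- (sa == 1L & sb == 2L) | (sa == 2L & sb == 1L)
  sum(diff & !reversed) + reversal_cost * sum(reversed)
}
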