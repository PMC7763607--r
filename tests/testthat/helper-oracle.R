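# Independent brute-force fragment enumeration oracle.
#
# Enumerates every vertex subset of size <= max_atoms with utils::combn,
# keeps those whose induced subgraph is connected and is a path, a chordless
# cycle, or a single-branch-point tree, and assembles canonical keys directly
# from the stated canonicalization rules. Shares nothing with the package's
# recursive enumerator.

oracle_count_fragments <- function(g, max_atoms, levels = 1:3) {
  labs <- fragbb::atom_labels(g, levels)
  n <- nrow(g$atoms)
  bsym <- c(single = "-", double = "=", triple = "#",
            aromatic = ":")[g$bonds$order]
  # bond lookup table
  bkey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  bonds <- setNames(bsym, bkey(g$bonds$from, g$bonds$to))
  adj <- lapply(seq_len(n), function(v) {
    c(g$bonds$to[g$bonds$from == v], g$bonds$from[g$bonds$to == v])
  })

  tally <- list()
  add <- function(key) tally[[key]] <<- (tally[[key]] %||% 0L) + 1L
  `%||%` <- function(a, b) if (is.null(a)) b else a

  classify_and_add <- function(sub) {
    s <- length(sub)
    # induced edges
    ed <- which(g$bonds$from %in% sub & g$bonds$to %in% sub)
    ef <- g$bonds$from[ed]; et <- g$bonds$to[ed]
    m <- length(ed)
    # connectivity by flood fill
    reach <- sub[1]
    repeat {
      nxt <- unique(c(et[ef %in% reach], ef[et %in% reach]))
      nxt <- setdiff(nxt, reach)
      if (!length(nxt)) break
      reach <- c(reach, nxt)
    }
    if (length(reach) != s) return(invisible())
    deg <- vapply(sub, function(v) sum(ef == v) + sum(et == v), integer(1))
    nbr <- function(v) setdiff(unique(c(et[ef == v], ef[et == v])), v)

    topo <- NULL
    order_atoms <- NULL
    if (s == 1) {
      topo <- "atom"
    } else if (m == s - 1 && max(deg) <= 2) {
      topo <- "path"
      cur <- sub[which(deg == 1)[1]]; prev <- -1
      order_atoms <- cur
      while (length(order_atoms) < s) {
        nx <- setdiff(nbr(cur), prev)
        prev <- cur; cur <- nx[1]
        order_atoms <- c(order_atoms, cur)
      }
    } else if (m == s - 1 && sum(deg >= 3) == 1) {
      topo <- "branch"
    } else if (m == s && all(deg == 2)) {
      topo <- "cycle"
      cur <- sub[1]; prev <- -1
      order_atoms <- cur
      while (length(order_atoms) < s) {
        nx <- setdiff(nbr(cur), prev)
        prev <- cur; cur <- nx[1]
        order_atoms <- c(order_atoms, cur)
      }
    } else {
      return(invisible())
    }

    for (lv in names(labs)) {
      lab <- labs[[lv]]
      body <- switch(topo,
        atom = paste0("A|", lab[sub]),
        path = {
          seqs <- lab[order_atoms]
          bs <- vapply(seq_len(s - 1), function(i) {
            bonds[[bkey(order_atoms[i], order_atoms[i + 1])]]
          }, character(1))
          fwd <- paste0(seqs[1],
                        paste0(bs, seqs[-1], collapse = ""))
          rev_ <- paste0(rev(seqs)[1],
                         paste0(rev(bs), rev(seqs)[-1], collapse = ""))
          paste0("P|", min(fwd, rev_))
        },
        cycle = {
          best <- NULL
          for (dir in c(1, -1)) {
            ord <- if (dir == 1) order_atoms else rev(order_atoms)
            for (st in seq_len(s)) {
              rot <- c(ord[st:s], ord[seq_len(st - 1)])
              str <- ""
              for (i in seq_len(s)) {
                nxt <- rot[if (i == s) 1 else i + 1]
                str <- paste0(str, lab[rot[i]], bonds[[bkey(rot[i], nxt)]])
              }
              if (is.null(best) || str < best) best <- str
            }
          }
          paste0("R|", best)
        },
        branch = {
          center <- sub[which(deg >= 3)]
          rays <- vapply(nbr(center), function(first) {
            ray <- bonds[[bkey(center, first)]]
            prev <- center; cur <- first
            repeat {
              ray <- paste0(ray, lab[cur])
              nx <- setdiff(nbr(cur), prev)
              if (!length(nx)) break
              ray <- paste0(ray, bonds[[bkey(cur, nx[1])]])
              prev <- cur; cur <- nx[1]
            }
            ray
          }, character(1))
          paste0("B|", lab[center],
                 paste0("(", sort(rays), ")", collapse = ""))
        }
      )
      add(paste0(lv, "|", body))
    }
  }

  for (s in seq_len(min(max_atoms, n))) {
    subs <- utils::combn(n, s, simplify = FALSE)
    for (sub in subs) classify_and_add(sub)
  }
  out <- tibble::tibble(key = names(tally),
                        count = as.integer(unlist(tally)))
  out[order(out$key), ]
}

# Random molecule-like graph: random spanning tree on n <= 10 vertices plus
# up to two extra edges, random elements / bond types / decorations. The
# enumerator only reads graph structure and labels, so chemical plausibility
# is irrelevant here.
random_molgraph <- function(seed) {
  set.seed(seed)
  n <- sample(2:10, 1)
  from <- integer(0); to <- integer(0)
  for (v in 2:n) {
    from <- c(from, sample(v - 1, 1)); to <- c(to, v)
  }
  n_extra <- sample(0:2, 1)
  for (k in seq_len(n_extra)) {
    pair <- sample(n, 2)
    a <- min(pair); b <- max(pair)
    dup <- any((from == a & to == b) | (from == b & to == a))
    if (!dup) { from <- c(from, a); to <- c(to, b) }
  }
  m <- length(from)
  orders <- sample(c("single", "double", "triple", "aromatic"), m,
                   replace = TRUE, prob = c(0.6, 0.2, 0.05, 0.15))
  deg <- tabulate(c(from, to), n)
  atoms <- tibble::tibble(
    element = sample(c("C", "N", "O", "S"), n, replace = TRUE,
                     prob = c(0.6, 0.2, 0.15, 0.05)),
    formal_charge = sample(c(0L, 0L, 0L, 1L, -1L), n, replace = TRUE),
    n_hydrogens = sample(0:3, n, replace = TRUE),
    valence_state = deg + sample(0:2, n, replace = TRUE),
    aromatic = sample(c(TRUE, FALSE), n, replace = TRUE),
    degree = deg
  )
  bonds <- tibble::tibble(
    from = from, to = to, order = orders,
    aromatic = orders == "aromatic",
    order_kekule = ifelse(orders == "double", 2L,
                          ifelse(orders == "triple", 3L, 1L))
  )
  structure(list(id = paste0("rnd", seed), atoms = atoms, bonds = bonds),
            class = "molgraph")
}
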