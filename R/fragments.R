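#' Multi-level atom labels for fragment classification
#'
#' Level 1 is the element alone; level 2 adds the pattern of incident
#' heavy-atom bond types and the aromaticity flag; level 3 further adds the
#' valence state, hydrogen count and formal charge. Each level refines the one
#' below it (the level-3 label string extends the level-2 string, which
#' extends level 1), so pooled counts are consistent across levels.
#'
#' Labels use only `[A-Za-z0-9.]` so they can be concatenated with the bond
#' symbols `- = # :` and the delimiters `( ) |` in canonical fragment keys.
#'
#' @param g A `molgraph`.
#' @param levels Integer subset of `1:3`.
#' @return Named list of per-atom character vectors, one per level.
#' @export
atom_labels <- function(g, levels = 1:3) {
  stopifnot(all(levels %in% 1:3))
  a <- g$atoms
  n <- nrow(a)
  out <- list()
  if (1 %in% levels) out[["L1"]] <- a$element
  if (any(c(2, 3) %in% levels)) {
    # bond pattern: sorted letters of incident heavy-bond types
    sym <- c(single = "s", double = "d", triple = "t", aromatic = "a")
    pat <- rep("", n)
    if (nrow(g$bonds)) {
      for (e in seq_len(nrow(g$bonds))) {
        s <- sym[[g$bonds$order[e]]]
        pat[g$bonds$from[e]] <- paste0(pat[g$bonds$from[e]], s)
        pat[g$bonds$to[e]] <- paste0(pat[g$bonds$to[e]], s)
      }
      pat <- vapply(strsplit(pat, ""), function(x) {
        paste(sort(x), collapse = "")
      }, character(1))
    }
    l2 <- paste0(a$element, ".", pat, ".", ifelse(a$aromatic, "ar", "al"))
    if (2 %in% levels) out[["L2"]] <- l2
    if (3 %in% levels) {
      chg <- ifelse(a$formal_charge == 0, "",
                    paste0(".", ifelse(a$formal_charge > 0, "p", "m"),
                           abs(a$formal_charge)))
      out[["L3"]] <- paste0(l2, ".v", a$valence_state, ".h", a$n_hydrogens, chg)
    }
  }
  out[order(names(out))]
}

bond_symbols <- function(g) {
  c(single = "-", double = "=", triple = "#", aromatic = ":")[g$bonds$order]
}

#' Count substructural fragments of a molecular graph
#'
#' Enumerates every connected induced subgraph of up to `max_atoms` heavy
#' atoms whose topology is a linear path, a chordless ring, or a branch (a
#' tree with exactly one atom of degree three or more), and counts occurrences
#' per canonical fragment key at each requested classification level. Each
#' distinct atom subset is counted once, regardless of traversal direction.
#'
#' @param g A `molgraph`.
#' @param max_atoms Maximum fragment size in heavy atoms (1-12).
#' @param levels Classification levels to generate, subset of `1:3`.
#' @return A tibble with columns `key` and `count`, sorted by key. Keys look
#'   like `L1|P|C-C-O` (level, topology `A`tom/`P`ath/`R`ing/`B`ranch, body).
#' @export
count_fragments <- function(g, max_atoms = 8, levels = 1:3) {
  stopifnot(inherits(g, "molgraph"), max_atoms >= 1, max_atoms <= 12)
  n <- nrow(g$atoms)
  if (n == 0) return(tibble::tibble(key = character(0), count = integer(0)))
  labs <- atom_labels(g, levels)
  bm <- as.matrix(g$bonds[, c("from", "to")])
  storage.mode(bm) <- "integer"
  if (nrow(bm) == 0) bm <- matrix(integer(0), ncol = 2)
  counts <- count_fragments_cpp(n, bm, bond_symbols(g), unname(labs),
                                names(labs), as.integer(max_atoms))
  tibble::tibble(key = names(counts), count = as.integer(counts))
}

#' Parse canonical fragment keys into their components
#'
#' @param key Character vector of fragment keys.
#' @return Tibble with `key`, `level`, `topology`, `body`.
#' @export
fragment_key_info <- function(key) {
  ok <- grepl("^L[0-9]+\\|[APRB]\\|", key)
  level <- rep(NA_integer_, length(key))
  topo <- rep(NA_character_, length(key))
  body <- rep(NA_character_, length(key))
  if (any(ok)) {
    parts <- strsplit(key[ok], "|", fixed = TRUE)
    level[ok] <- as.integer(sub("^L", "", vapply(parts, `[`, "", 1)))
    topo[ok] <- c(A = "atom", P = "path", R = "cycle",
                  B = "branch")[vapply(parts, `[`, "", 2)]
    body[ok] <- vapply(parts, function(p) paste(p[-(1:2)], collapse = "|"),
                       character(1))
  }
  tibble::tibble(key = key, level = level, topology = topo, body = body)
}

#' Project canonical fragment keys to a coarser classification level
#'
#' Strips the label decorations beyond the target level and
#' re-canonicalizes the fragment body (the canonical writing can change once
#' labels coarsen). Keys already at or below the target level are returned
#' unchanged; `NA` for malformed keys.
#'
#' @param keys Character vector of canonical fragment keys.
#' @param level Target classification level (1 or 2).
#' @return Character vector of projected keys.
#' @export
project_fragment_key <- function(keys, level = 1) {
  stopifnot(level %in% 1:2)
  info <- fragment_key_info(keys)
  vapply(seq_along(keys), function(i) {
    if (is.na(info$level[i])) return(NA_character_)
    if (info$level[i] <= level) return(keys[i])
    body <- project_labels(info$body[i], level)
    prefix <- paste0("L", level, "|")
    switch(info$topology[i],
      atom = paste0(prefix, "A|", body),
      path = paste0(prefix, "P|", canonical_path_body(body)),
      cycle = paste0(prefix, "R|", canonical_cycle_body(body)),
      branch = paste0(prefix, "B|", canonical_branch_body(body))
    )
  }, character(1))
}

# strip label decorations: level 1 keeps the element, level 2 keeps
# element.pattern.aromaticity
project_labels <- function(body, level) {
  if (level == 1) {
    gsub("([A-Za-z][a-z]?)\\.[A-Za-z0-9.]*", "\\1", body)
  } else {
    gsub("([A-Za-z][a-z]?\\.[a-z]*\\.a[lr])\\.[A-Za-z0-9.]*", "\\1", body)
  }
}

split_body_tokens <- function(body) {
  strsplit(body, "(?<=.)(?=[-=#:])|(?<=[-=#:])", perl = TRUE)[[1]]
}

canonical_path_body <- function(body) {
  toks <- split_body_tokens(body)
  min(body, paste(rev(toks), collapse = ""))
}

canonical_cycle_body <- function(body) {
  toks <- split_body_tokens(body)
  n <- length(toks) / 2
  best <- NULL
  for (dir in c(1, -1)) {
    for (st in seq_len(n)) {
      s <- ""
      for (i in seq_len(n)) {
        lab <- ((st - 1 + dir * (i - 1)) %% n) + 1
        bond <- if (dir == 1) lab else ((lab - 2) %% n) + 1
        s <- paste0(s, toks[2 * lab - 1], toks[2 * bond])
      }
      if (is.null(best) || s < best) best <- s
    }
  }
  best
}

canonical_branch_body <- function(body) {
  m <- regmatches(body, regexec("^([^(]+)(.*)$", body))[[1]]
  rays <- regmatches(m[3], gregexpr("\\(([^)]*)\\)", m[3]))[[1]]
  rays <- sort(gsub("[()]", "", rays))
  paste0(m[2], paste0("(", rays, ")", collapse = ""))
}

#' Build the compounds-by-fragments descriptor matrix
#'
#' The fragment catalog is the union of all fragments found in the dataset;
#' columns are ordered by canonical key so the matrix is deterministic.
#' Compounds whose structures cannot be parsed are excluded and reported.
#'
#' @param compounds Tibble with columns `id` and either a `graph` list column
#'   (from [parse_compounds()]) or a `smiles` column.
#' @param max_atoms Maximum fragment size in heavy atoms.
#' @param levels Classification levels, subset of `1:3`.
#' @return An object of class `descriptor_matrix`: list with `counts`
#'   (integer matrix, compounds x fragments), `compound_ids`, `catalog`
#'   (tibble of key metadata) and `rejects`.
#' @export
build_descriptor_matrix <- function(compounds, max_atoms = 8, levels = 1:3) {
  stopifnot(nrow(compounds) > 0)
  rejects <- tibble::tibble(id = character(0), reason = character(0))
  if (!"graph" %in% names(compounds)) {
    parsed <- parse_compounds(compounds)
    compounds <- parsed$compounds
    rejects <- parsed$rejects
    if (nrow(rejects)) {
      warning(sprintf("%d compound(s) failed to parse and were excluded",
                      nrow(rejects)), call. = FALSE)
    }
  }
  per <- lapply(compounds$graph, count_fragments,
                max_atoms = max_atoms, levels = levels)
  keys <- sort(unique(unlist(lapply(per, `[[`, "key"))))
  mat <- matrix(0L, nrow = nrow(compounds), ncol = length(keys),
                dimnames = list(compounds$id, keys))
  for (i in seq_along(per)) {
    mat[i, per[[i]]$key] <- per[[i]]$count
  }
  new_descriptor_matrix(mat, rejects = rejects,
                        max_atoms = max_atoms, levels = levels)
}

new_descriptor_matrix <- function(counts, rejects = NULL, max_atoms = NA,
                                  levels = NA) {
  structure(
    list(
      counts = counts,
      compound_ids = rownames(counts),
      catalog = fragment_key_info(colnames(counts)),
      rejects = rejects %||%
        tibble::tibble(id = character(0), reason = character(0)),
      max_atoms = max_atoms,
      levels = levels
    ),
    class = "descriptor_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat("<descriptor_matrix> ", nrow(x$counts), " compounds x ",
      ncol(x$counts), " fragments\n", sep = "")
  invisible(x)
}

#' @export
dim.descriptor_matrix <- function(x) dim(x$counts)

#' Remove rare fragments from a descriptor matrix
#'
#' Drops every fragment column whose count is nonzero in fewer than
#' `min_support` compounds. The default keeps fragments present in at least
#' five compounds, i.e. removes those present in four or fewer, which cannot
#' support general structure-property relationships.
#'
#' @param dm A `descriptor_matrix`.
#' @param min_support Minimum number of compounds a fragment must occur in.
#' @return A `descriptor_matrix` with the surviving columns.
#' @export
filter_rare <- function(dm, min_support = 5) {
  stopifnot(inherits(dm, "descriptor_matrix"))
  support <- colSums(dm$counts > 0)
  keep <- support >= min_support
  new_descriptor_matrix(dm$counts[, keep, drop = FALSE], rejects = dm$rejects,
                        max_atoms = dm$max_atoms, levels = dm$levels)
}

#' @describeIn build_descriptor_matrix Long-tibble view (nonzero cells only).
#' @param x A `descriptor_matrix`.
#' @param ... Unused.
#' @export
tidy.descriptor_matrix <- function(x, ...) {
  idx <- which(x$counts > 0, arr.ind = TRUE)
  tibble::tibble(
    id = rownames(x$counts)[idx[, 1]],
    key = colnames(x$counts)[idx[, 2]],
    count = x$counts[idx]
  ) |> dplyr::arrange(.data$id, .data$key)
}

#' Export / import a descriptor matrix as plain text
#'
#' `format = "tsv"` writes the dense matrix with a header of canonical keys
#' and row names in the first column; `"triplet"` writes a sparse
#' id/key/count table. Both round trip through [read_descriptor_matrix()].
#'
#' @param dm A `descriptor_matrix`.
#' @param path Output file path.
#' @param format `"tsv"` or `"triplet"`.
#' @export
write_descriptor_matrix <- function(dm, path, format = c("tsv", "triplet")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(id = rownames(dm$counts), dm$counts,
                     check.names = FALSE)
    readr::write_tsv(df, path)
  } else {
    readr::write_tsv(tidy(dm), path)
  }
  invisible(path)
}

#' @rdname write_descriptor_matrix
#' @export
read_descriptor_matrix <- function(path, format = c("tsv", "triplet")) {
  format <- match.arg(format)
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (format == "tsv") {
    mat <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(mat) <- "integer"
    rownames(mat) <- df$id
  } else {
    ids <- unique(df$id)
    keys <- sort(unique(df$key))
    mat <- matrix(0L, length(ids), length(keys),
                  dimnames = list(ids, keys))
    mat[cbind(match(df$id, ids), match(df$key, keys))] <- as.integer(df$count)
  }
  new_descriptor_matrix(mat)
}
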