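#' Blood-brain distribution coefficient from concentrations
#'
#' LogBB is the decimal logarithm of the ratio of the total compound
#' concentration in brain tissue to the total concentration in blood plasma.
#' Both concentrations must be strictly positive and in the same units.
#'
#' @param c_brain Numeric vector of brain concentrations.
#' @param c_plasma Numeric vector of plasma concentrations (same units).
#' @return Numeric vector of LogBB values (log10 units).
#' @examples
#' compute_logbb(100, 1)  # 2
#' @export
compute_logbb <- function(c_brain, c_plasma) {
  if (!is.numeric(c_brain) || !is.numeric(c_plasma)) {
    stop("concentrations must be numeric", call. = FALSE)
  }
  if (any(!is.finite(c_brain)) || any(!is.finite(c_plasma)) ||
      any(c_brain <= 0) || any(c_plasma <= 0)) {
    stop("concentrations must be finite and strictly positive", call. = FALSE)
  }
  log10(c_brain / c_plasma)
}

# -- OpenBabel plumbing -------------------------------------------------------

ob_convert <- function(from, to, text, opts = character()) {
  options <- NULL
  if (length(opts)) options <- data.frame(names = opts, args = "")
  ChemmineOB::convertFormat(from, to, source = text, options = options)
}

# Read an SDF text blob into a ChemmineR SDFset (read.SDFset only reads files).
read_sdf_text <- function(text) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(text, tf)
  suppressWarnings(ChemmineR::read.SDFset(tf))
}

# old MDL charge codes -> formal charges
.mdl_charge <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
                 `6` = -2, `7` = -3)

#' Parse a chemical structure into a typed molecular graph
#'
#' Accepts a SMILES string or an SDF (V2000) molblock and returns a heavy-atom
#' graph: hydrogens are folded into per-atom counts, formal charges retained,
#' and aromaticity perceived by one uniform ring-based scheme. When the input
#' contains several disconnected components (salts, mixtures) only the largest
#' component is kept.
#'
#' @param x A single SMILES string, or the text of one SDF molblock.
#' @param dialect `"smiles"` or `"sdf"`.
#' @param id Compound identifier stored on the graph.
#' @return An object of class `molgraph` with elements `id`, `atoms`
#'   (tibble: `element`, `formal_charge`, `n_hydrogens`, `valence_state`,
#'   `aromatic`, `degree`) and `bonds` (tibble: `from`, `to`, `order`,
#'   `aromatic`, `order_kekule`).
#' @export
parse_structure <- function(x, dialect = c("smiles", "sdf"), id = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(id)) id <- if (dialect == "smiles") x else "mol1"
  sdf_txt <- tryCatch(
    {
      if (dialect == "smiles") {
        ob_convert("SMI", "SDF", paste0(x, "\n"), opts = "h")
      } else {
        txt <- paste(x, collapse = "\n")
        if (!grepl("\\$\\$\\$\\$", txt)) txt <- paste0(txt, "\n$$$$\n")
        ob_convert("SDF", "SDF", txt, opts = "h")
      }
    },
    error = function(e) ""
  )
  if (!nzchar(sdf_txt) || !grepl("V2000", sdf_txt, fixed = TRUE)) {
    stop(structure(
      class = c("fragbb_parse_error", "error", "condition"),
      list(message = paste0("could not parse structure '", id, "'"),
           call = NULL, id = id)
    ))
  }
  sdf <- read_sdf_text(sdf_txt)[[1]]
  g <- molgraph_from_sdf(sdf, id = id)
  if (nrow(g$atoms) == 0) {
    stop(structure(
      class = c("fragbb_parse_error", "error", "condition"),
      list(message = paste0("structure '", id, "' has no heavy atoms"),
           call = NULL, id = id)
    ))
  }
  g
}

# Build a molgraph from a ChemmineR SDF object with explicit hydrogens.
molgraph_from_sdf <- function(sdf, id) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_[0-9]+$", "", rownames(ab))
  n_all <- length(elements)
  charge_code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, n_all)
  charges <- unname(.mdl_charge[as.character(charge_code)])
  charges[is.na(charges)] <- 0

  if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1)
  if (ncol(bb) < 3) bb <- cbind(bb, matrix(0L, nrow(bb), 3 - ncol(bb)))
  e_from <- as.integer(bb[, 1])
  e_to <- as.integer(bb[, 2])
  e_ord <- as.integer(bb[, 3])
  # bond-less molecules surface as a single all-zero row
  real <- e_from > 0 & e_to > 0
  e_from <- e_from[real]; e_to <- e_to[real]; e_ord <- e_ord[real]

  # aromaticity: atoms of any ring flagged aromatic by the ring perceiver
  arom_atoms <- integer(0)
  arom_ring_list <- list()
  if (length(e_from) && any(elements != "H")) {
    rr <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf, upper = 14, type = "all",
                                        arom = TRUE, inner = FALSE)),
      error = function(e) NULL
    )
    if (!is.null(rr) && length(rr$RINGS)) {
      keep <- which(unlist(rr$AROMATIC))
      for (k in keep) {
        ring <- as.integer(sub("^.*_", "", rr$RINGS[[k]]))
        arom_ring_list[[length(arom_ring_list) + 1L]] <- ring
        arom_atoms <- union(arom_atoms, ring)
      }
    }
  }

  heavy <- which(elements != "H")
  remap <- integer(n_all)
  remap[heavy] <- seq_along(heavy)

  n_h <- integer(length(heavy))
  deg <- integer(length(heavy))
  val <- integer(length(heavy))
  keep_bond <- logical(length(e_from))
  for (e in seq_along(e_from)) {
    a <- e_from[e]; b <- e_to[e]
    ha <- elements[a] != "H"; hb <- elements[b] != "H"
    if (ha && hb) {
      keep_bond[e] <- TRUE
      deg[remap[a]] <- deg[remap[a]] + 1L
      deg[remap[b]] <- deg[remap[b]] + 1L
      val[remap[a]] <- val[remap[a]] + e_ord[e]
      val[remap[b]] <- val[remap[b]] + e_ord[e]
    } else if (ha && !hb) {
      n_h[remap[a]] <- n_h[remap[a]] + 1L
      val[remap[a]] <- val[remap[a]] + 1L
    } else if (!ha && hb) {
      n_h[remap[b]] <- n_h[remap[b]] + 1L
      val[remap[b]] <- val[remap[b]] + 1L
    }
  }

  bf <- remap[e_from[keep_bond]]
  bt <- remap[e_to[keep_bond]]
  bo <- e_ord[keep_bond]

  atom_arom <- logical(length(heavy))
  atom_arom[remap[intersect(arom_atoms, heavy)]] <- TRUE
  bond_arom <- logical(length(bf))
  for (ring in arom_ring_list) {
    r <- remap[ring]
    for (e in seq_along(bf)) {
      if (bf[e] %in% r && bt[e] %in% r) {
        # bond must be consecutive in the ring to belong to it
        i <- match(bf[e], r); j <- match(bt[e], r)
        if (abs(i - j) == 1L || abs(i - j) == length(r) - 1L) {
          bond_arom[e] <- TRUE
        }
      }
    }
  }

  atoms <- tibble::tibble(
    element = elements[heavy],
    formal_charge = as.integer(charges[heavy]),
    n_hydrogens = n_h,
    valence_state = val,
    aromatic = atom_arom,
    degree = deg
  )
  bonds <- tibble::tibble(
    from = bf, to = bt,
    order = dplyr::case_when(
      bond_arom ~ "aromatic",
      bo == 1L ~ "single",
      bo == 2L ~ "double",
      bo == 3L ~ "triple",
      TRUE ~ "single"
    ),
    aromatic = bond_arom,
    order_kekule = bo
  )

  g <- structure(list(id = id, atoms = atoms, bonds = bonds),
                 class = "molgraph")
  keep_largest_component(g)
}

# retain only the largest connected component (ties: component with the
# lowest atom index); standard salt/mixture curation
keep_largest_component <- function(g) {
  n <- nrow(g$atoms)
  if (n <= 1 || nrow(g$bonds) == 0) {
    if (n > 1) {  # n isolated atoms: keep the first
      return(subset_molgraph(g, 1L))
    }
    return(g)
  }
  ig <- igraph::graph_from_edgelist(cbind(g$bonds$from, g$bonds$to),
                                    directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0, n - igraph::vcount(ig)))
  comp <- igraph::components(ig)
  if (comp$no == 1) return(g)
  best <- which.max(comp$csize)
  subset_molgraph(g, which(comp$membership == best))
}

subset_molgraph <- function(g, keep) {
  keep <- sort(keep)
  remap <- integer(nrow(g$atoms))
  remap[keep] <- seq_along(keep)
  bsel <- g$bonds$from %in% keep & g$bonds$to %in% keep
  bonds <- g$bonds[bsel, , drop = FALSE]
  bonds$from <- remap[bonds$from]
  bonds$to <- remap[bonds$to]
  g$atoms <- g$atoms[keep, , drop = FALSE]
  g$bonds <- bonds
  # recompute degrees on the kept component
  deg <- integer(nrow(g$atoms))
  for (e in seq_len(nrow(bonds))) {
    deg[bonds$from[e]] <- deg[bonds$from[e]] + 1L
    deg[bonds$to[e]] <- deg[bonds$to[e]] + 1L
  }
  g$atoms$degree <- deg
  g
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", x$id, ": ", nrow(x$atoms), " heavy atoms, ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' Write a molecular graph as an SDF (V2000) molblock
#'
#' Hydrogens stay implicit; bond orders are written kekulized. The block round
#' trips through [parse_structure()] to an identical canonical structure key.
#'
#' @param g A `molgraph`.
#' @return A single string holding the molblock (terminated by `$$$$`).
#' @export
write_sdf_block <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  n <- nrow(g$atoms); m <- nrow(g$bonds)
  head <- c(g$id, "  fragbb", "",
            sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   0, 0, 0, g$atoms$element)
  bonds <- if (m) {
    sprintf("%3d%3d%3d  0  0  0  0", g$bonds$from, g$bonds$to,
            g$bonds$order_kekule)
  } else character(0)
  chg <- which(g$atoms$formal_charge != 0)
  chg_lines <- if (length(chg)) {
    vapply(chg, function(i) {
      sprintf("M  CHG  1 %3d %3d", i, g$atoms$formal_charge[i])
    }, character(1))
  } else character(0)
  paste(c(head, atoms, bonds, chg_lines, "M  END", "$$$$"), collapse = "\n")
}

#' Canonical structure key
#'
#' Returns a key that is identical for any two structures that are isomorphic
#' with the same atom and bond typing, independent of atom input order or
#' source format (canonical SMILES of the largest component).
#'
#' @param x A `molgraph`, or a character vector of SMILES strings.
#' @return Character vector of canonical keys (`NA` where parsing failed).
#' @export
canonical_structure_key <- function(x) {
  if (inherits(x, "molgraph")) {
    out <- ob_convert("SDF", "CAN", write_sdf_block(x), opts = "r")
    return(strip_smiles_title(out))
  }
  if (!is.character(x)) stop("x must be a molgraph or SMILES strings",
                             call. = FALSE)
  # batch through OpenBabel; row-index titles keep alignment when rows fail
  src <- paste0(x, " m", seq_along(x), collapse = "\n")
  out <- tryCatch(ob_convert("SMI", "CAN", paste0(src, "\n"), opts = "r"),
                  error = function(e) "")
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  keys <- rep(NA_character_, length(x))
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(parts) >= 2) {
      idx <- suppressWarnings(as.integer(sub("^m", "", parts[length(parts)])))
      if (!is.na(idx)) keys[idx] <- parts[1]
    }
  }
  # OpenBabel stops a batch at the first invalid molecule; retry stragglers
  # one at a time so a single bad row cannot shadow the rows after it
  for (i in which(is.na(keys))) {
    out <- tryCatch(ob_convert("SMI", "CAN", paste0(x[i], "\n"), opts = "r"),
                    error = function(e) "")
    if (nzchar(out)) keys[i] <- strip_smiles_title(out)
  }
  keys
}

strip_smiles_title <- function(out) {
  ln <- strsplit(out, "\n", fixed = TRUE)[[1]]
  ln <- ln[nzchar(trimws(ln))]
  if (!length(ln)) return(NA_character_)
  strsplit(trimws(ln[1]), "[ \t]+")[[1]][1]
}

# -- compound tables ----------------------------------------------------------

#' Read a compound table from CSV
#'
#' Expected columns: `id`, `smiles` and optionally `logbb` (log10 units).
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `id`, `smiles`, `logbb`.
#' @export
read_compounds_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("id", "smiles") %in% names(df))) {
    stop("CSV must contain columns 'id' and 'smiles'", call. = FALSE)
  }
  if (!"logbb" %in% names(df)) df$logbb <- NA_real_
  df$id <- as.character(df$id)
  tibble::as_tibble(df[, c("id", "smiles", "logbb")])
}

#' Read a compound table from an SDF (V2000) file
#'
#' Compound identifiers are taken from the molblock title line (or generated);
#' a `logbb` data field is picked up when present.
#'
#' @param path Path to an SDF file.
#' @param logbb_field Name of the SDF data field holding the endpoint.
#' @return A tibble with columns `id`, `smiles` (canonical), `logbb`,
#'   and a `graph` list column of parsed `molgraph` objects.
#' @export
read_compounds_sdf <- function(path, logbb_field = "logbb") {
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  n <- length(sdfs)
  ids <- character(n); graphs <- vector("list", n); vals <- rep(NA_real_, n)
  smi <- character(n)
  for (i in seq_len(n)) {
    s <- sdfs[[i]]
    hdr <- ChemmineR::header(s)
    ids[i] <- if (nzchar(trimws(hdr[1]))) trimws(hdr[1]) else paste0("mol", i)
    db <- ChemmineR::datablock(s)
    if (logbb_field %in% names(db)) {
      vals[i] <- suppressWarnings(as.numeric(db[[logbb_field]]))
    }
    block <- paste(c(ChemmineR::sdf2str(s)), collapse = "\n")
    graphs[[i]] <- parse_structure(block, dialect = "sdf", id = ids[i])
    smi[i] <- canonical_structure_key(graphs[[i]])
  }
  tibble::tibble(id = ids, smiles = smi, logbb = vals, graph = graphs)
}

#' Parse all structures of a compound table
#'
#' Adds a `graph` list column with parsed heavy-atom graphs; rows that fail
#' to parse are returned separately.
#'
#' @param compounds Tibble with columns `id` and `smiles`.
#' @return A list with `compounds` (input rows that parsed, plus `graph`) and
#'   `rejects` (tibble `id`, `reason`).
#' @export
parse_compounds <- function(compounds) {
  stopifnot(all(c("id", "smiles") %in% names(compounds)))
  n <- nrow(compounds)
  # one OpenBabel batch call; row-index titles keep the alignment
  src <- paste0(compounds$smiles, " m", seq_len(n), collapse = "\n")
  sdf_txt <- tryCatch(ob_convert("SMI", "SDF", paste0(src, "\n"), opts = "h"),
                      error = function(e) "")
  graphs <- vector("list", n)
  if (nzchar(sdf_txt)) {
    sdfs <- read_sdf_text(sdf_txt)
    for (i in seq_along(sdfs)) {
      s <- sdfs[[i]]
      idx <- suppressWarnings(
        as.integer(sub("^m", "", trimws(ChemmineR::header(s)[1])))
      )
      if (is.na(idx) || idx < 1 || idx > n) next
      # single-bracket assignment: a NULL result must keep the slot, not
      # delete it and shift every later index
      graphs[idx] <- list(tryCatch(
        {
          g <- molgraph_from_sdf(s, id = compounds$id[idx])
          if (nrow(g$atoms) == 0) NULL else g
        },
        error = function(e) NULL
      ))
    }
  }
  # retry rows missed by the batch (OpenBabel aborts at an invalid molecule)
  for (i in which(vapply(graphs, is.null, logical(1)))) {
    graphs[i] <- list(tryCatch(
      parse_structure(compounds$smiles[i], "smiles", id = compounds$id[i]),
      error = function(e) NULL
    ))
  }
  ok <- !vapply(graphs, is.null, logical(1))
  out <- compounds[ok, , drop = FALSE]
  out$graph <- graphs[ok]
  rejects <- tibble::tibble(id = compounds$id[!ok], reason = "parse_failure")
  list(compounds = tibble::as_tibble(out), rejects = rejects)
}
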