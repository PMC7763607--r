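#' Default building-block grammar for synthetic compounds
#'
#' Blocks are complete SMILES units whose final atom can accept at least one
#' further bond, so concatenating blocks always yields a valid molecule. The
#' set covers the moiety classes whose permeability effects the package's
#' interpretation layer is meant to recover: alkyl chains, aromatic rings,
#' halogenated aromatics, amines, ethers, carboxyl groups, amides, aliphatic
#' chlorides and sulfonamides.
#'
#' @return Tibble with columns `block` (SMILES) and `weight`.
#' @export
default_grammar <- function() {
  tibble::tribble(
    ~block,            ~weight,
    "C",               3.0,
    "CC",              2.0,
    "CCC",             1.0,
    "c1ccccc1",        2.0,
    "c1ccc(F)cc1",     0.8,
    "c1ccc(Cl)cc1",    0.8,
    "N",               1.5,
    "O",               1.5,
    "C(=O)O",          1.0,
    "C(=O)N",          1.0,
    "C(Cl)",           0.6,
    "S(=O)(=O)N",      0.5
  )
}

# Locate the canonical key of a specific fragment inside a probe molecule:
# the unique fragment of the stated level / topology / size, optionally
# restricted to keys containing a substring. Keeps planted coefficients
# independent of the key format.
probe_fragment_key <- function(smiles, level, n_atoms, topology,
                               containing = NULL) {
  g <- parse_structure(smiles, "smiles", id = smiles)
  fc <- count_fragments(g, max_atoms = n_atoms, levels = level)
  info <- fragment_key_info(fc$key)
  hit <- info$level == level & info$topology == topology
  sizes <- vapply(seq_len(nrow(info)), function(i) {
    fragment_size_from_key(info$topology[i], info$body[i])
  }, numeric(1))
  hit <- hit & sizes == n_atoms
  if (!is.null(containing)) hit <- hit & grepl(containing, info$key,
                                               fixed = TRUE)
  keys <- info$key[hit]
  if (length(keys) != 1) {
    stop(sprintf("probe '%s' does not isolate a unique fragment (%d hits)",
                 smiles, length(keys)), call. = FALSE)
  }
  keys
}

# number of atoms in a fragment body (labels alternate with bond symbols)
fragment_size_from_key <- function(topology, body) {
  if (topology == "atom") return(1)
  n_bonds <- nchar(gsub("[^-=#:]", "", body))
  switch(topology,
    path = n_bonds + 1,
    cycle = n_bonds,
    branch = n_bonds + 1
  )
}

#' Default planted fragment coefficients
#'
#' Effects in log units per fragment occurrence, chosen to mirror the
#' qualitative structure-permeability patterns the model family is expected
#' to learn: carboxyl, amide and sulfonamide groups and aliphatic chlorine
#' depress LogBB; aliphatic amines, ethers, fluorine, aromatic carbon and
#' aromatic chlorine raise it. Keys are resolved from probe molecules at
#' call time so they track the package's canonical key format.
#'
#' @return Tibble with columns `key` and `coefficient`.
#' @export
default_coefficients <- function() {
  tibble::tibble(
    key = c(
      probe_fragment_key("OC=O", 1, 3, "path"),          # carboxyl O-C=O
      probe_fragment_key("NC=O", 1, 3, "path"),          # amide N-C=O
      "L1|A|N",
      "L1|A|O",
      "L1|A|F",
      "L1|A|S",
      probe_fragment_key("c1ccccc1", 1, 2, "path"),      # aromatic C:C
      probe_fragment_key("ClC", 2, 2, "path"),           # aliphatic C-Cl
      probe_fragment_key("Clc1ccccc1", 2, 2, "path",
                         containing = "Cl")              # aromatic C-Cl
    ),
    coefficient = c(-0.70, -0.55, 0.45, 0.18, 0.35, -0.60, 0.05,
                    -0.45, 0.25)
  )
}

#' Synthetic dataset specification
#'
#' @param n_compounds Number of molecules to generate.
#' @param grammar Building-block tibble, see [default_grammar()].
#' @param coefficients Planted effects tibble (`key`, `coefficient`).
#' @param intercept Baseline endpoint value (log units).
#' @param nonlinearity `"none"` for a purely linear endpoint or `"tanh"` for
#'   a mild saturating squash of the linear predictor.
#' @param noise_sd Gaussian noise standard deviation (log units).
#' @param clip_range Endpoint clipped to this interval, emulating the
#'   span of a curated LogBB modeling dataset.
#' @param blocks_range Minimum and maximum number of blocks per molecule.
#' @param max_atoms,levels Featurization used to evaluate the planted
#'   effects.
#' @param seed Integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 500, grammar = default_grammar(),
                           coefficients = default_coefficients(),
                           intercept = -0.5,
                           nonlinearity = c("none", "tanh"),
                           noise_sd = 0.3, clip_range = c(-2.15, 1.7),
                           blocks_range = c(2, 6),
                           max_atoms = 8, levels = 1:2, seed = 42) {
  nonlinearity <- match.arg(nonlinearity)
  stopifnot(n_compounds >= 1, noise_sd >= 0, nrow(grammar) >= 1)
  structure(list(n_compounds = n_compounds, grammar = grammar,
                 coefficients = coefficients, intercept = intercept,
                 nonlinearity = nonlinearity, noise_sd = noise_sd,
                 clip_range = clip_range, blocks_range = blocks_range,
                 max_atoms = max_atoms, levels = levels, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic compound dataset with known fragment effects
#'
#' Molecules are assembled by concatenating building-block SMILES (which
#' guarantees chemical validity), the endpoint is a function of planted
#' fragment-count effects plus Gaussian noise, clipped to the configured
#' range. Deterministic given the seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_dataset` with `compounds` (tibble
#'   `id`, `smiles`, `logbb`, `graph`), `truth` (the planted coefficients)
#'   and `spec`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_compounds
  smiles <- withr::with_seed(spec$seed, {
    out <- character(0)
    tries <- 0
    while (length(out) < n && tries < 60 * n) {
      k <- sample(seq(spec$blocks_range[1], spec$blocks_range[2]), 1)
      s <- paste(sample(spec$grammar$block, k, replace = TRUE,
                        prob = spec$grammar$weight), collapse = "")
      if (!s %in% out) out <- c(out, s)
      tries <- tries + 1
    }
    out
  })
  if (length(smiles) < n) {
    stop("grammar too small to generate the requested number of unique molecules",
         call. = FALSE)
  }
  compounds <- tibble::tibble(id = sprintf("SYN%04d", seq_len(n)),
                              smiles = smiles)
  parsed <- parse_compounds(compounds)
  if (nrow(parsed$rejects) > 0) {
    stop("grammar produced unparseable molecules: ",
         paste(parsed$rejects$id, collapse = ", "), call. = FALSE)
  }
  compounds <- parsed$compounds

  lin <- vapply(compounds$graph, function(g) {
    fc <- count_fragments(g, max_atoms = spec$max_atoms,
                          levels = spec$levels)
    cnt <- stats::setNames(fc$count, fc$key)
    hit <- spec$coefficients$key %in% names(cnt)
    spec$intercept + sum(spec$coefficients$coefficient[hit] *
                           cnt[spec$coefficients$key[hit]])
  }, numeric(1))
  lin <- switch(spec$nonlinearity,
    none = lin,
    tanh = 2.2 * tanh(lin / 2.2)
  )
  noise <- withr::with_seed(spec$seed + 1L,
                            rnorm(n, sd = spec$noise_sd))
  compounds$logbb <- pmin(pmax(lin + noise, spec$clip_range[1]),
                          spec$clip_range[2])
  structure(list(compounds = compounds, truth = spec$coefficients,
                 spec = spec),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", nrow(x$compounds), " compounds, ",
      nrow(x$truth), " planted fragment effects\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset in the standard compound-table schema
#'
#' Produces the same CSV layout as real datasets (`id`, `smiles`, `logbb`)
#' plus a ground-truth sidecar (`key`, `coefficient`).
#'
#' @param x A `synthetic_dataset`.
#' @param path Output CSV path; the sidecar gets the suffix `_truth.csv`.
#' @export
write_synthetic_csv <- function(x, path) {
  readr::write_csv(x$compounds[, c("id", "smiles", "logbb")], path)
  readr::write_csv(x$truth, sub("\\.csv$", "_truth.csv", path))
  invisible(path)
}

#' Hand-checked micro-fixtures for the fragment enumerator
#'
#' A bundled set of small molecules whose fragment counts were enumerated by
#' hand and recorded as plain-text files under `extdata`.
#'
#' @return A list with `compounds` (tibble `name`, `smiles`) and
#'   `expected_counts` (tibble `name`, `key`, `count`, at level 1 and the
#'   recorded `max_atoms`).
#' @export
make_toy_fixtures <- function() {
  cmp <- readr::read_csv(
    system.file("extdata", "toy_compounds.csv", package = "fragbb"),
    show_col_types = FALSE
  )
  counts <- readr::read_csv(
    system.file("extdata", "toy_fragment_counts.csv", package = "fragbb"),
    show_col_types = FALSE
  )
  list(compounds = tibble::as_tibble(cmp),
       expected_counts = tibble::as_tibble(counts))
}
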