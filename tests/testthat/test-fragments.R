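counts_as_named <- function(fc) {
  v <- stats::setNames(fc$count, fc$key)
  v[order(names(v))]
}
sort_named <- function(v) v[order(names(v))]

test_that("fragment counts match the hand-enumerated toy fixtures", {
  fx <- make_toy_fixtures()
  expect_gte(nrow(fx$compounds), 10)
  graphs <- lapply(fx$compounds$smiles, parse_structure)
  names(graphs) <- fx$compounds$name
  for (nm in unique(fx$expected_counts$name)) {
    exp_df <- fx$expected_counts[fx$expected_counts$name == nm, ]
    got <- count_fragments(graphs[[nm]], max_atoms = exp_df$max_atoms[1],
                           levels = 1)
    expect_equal(counts_as_named(got),
                 sort_named(stats::setNames(as.integer(exp_df$count),
                                            exp_df$key)),
                 label = paste("counts for", nm))
  }
})

test_that("single-atom molecules yield exactly one fragment per level", {
  g <- parse_structure("C")
  for (lv in 1:3) {
    fc <- count_fragments(g, max_atoms = 8, levels = lv)
    expect_equal(nrow(fc), 1)
    expect_equal(fc$count, 1L)
  }
})

test_that("enumeration equals the exhaustive induced-subgraph oracle on random graphs", {
  for (seed in 1:200) {
    g <- random_molgraph(seed)
    got <- count_fragments(g, max_atoms = 10, levels = 1:3)
    want <- oracle_count_fragments(g, max_atoms = 10, levels = 1:3)
    expect_equal(counts_as_named(got), counts_as_named(want),
                 label = paste("oracle agreement for random graph", seed))
  }
})

test_that("fragment counts are invariant under atom relabeling", {
  for (seed in c(3, 17, 42)) {
    g <- random_molgraph(seed)
    n <- nrow(g$atoms)
    perm <- sample(n)
    gp <- g
    gp$atoms <- g$atoms[order(perm), ]
    gp$bonds$from <- perm[g$bonds$from]
    gp$bonds$to <- perm[g$bonds$to]
    expect_equal(counts_as_named(count_fragments(gp, 8, 1:3)),
                 counts_as_named(count_fragments(g, 8, 1:3)))
  }
})

test_that("level-3 counts aggregate to level-1 counts (refinement hierarchy)", {
  # project each decorated label to its element, then re-canonicalize the
  # body (the canonical writing can change once labels lose their suffixes)
  strip_labels <- function(s) {
    gsub("([A-Za-z][a-z]?)\\.[A-Za-z0-9.]*", "\\1", s)
  }
  recanonicalize <- function(key) {
    info <- fragment_key_info(sub("^L3", "L1", key))
    body <- strip_labels(info$body)
    if (info$topology == "atom") return(paste0("L1|A|", body))
    if (info$topology == "path") {
      toks <- strsplit(body, "(?<=.)(?=[-=#:])|(?<=[-=#:])", perl = TRUE)[[1]]
      rev_body <- paste(rev(toks), collapse = "")
      return(paste0("L1|P|", min(body, rev_body)))
    }
    if (info$topology == "cycle") {
      toks <- strsplit(body, "(?<=.)(?=[-=#:])|(?<=[-=#:])", perl = TRUE)[[1]]
      n <- length(toks) / 2  # label, bond alternating
      best <- NULL
      for (dir in c(1, -1)) {
        for (st in seq_len(n)) {
          idx_lab <- ((st - 1 + dir * (seq_len(n) - 1)) %% n) + 1
          s <- ""
          for (i in seq_len(n)) {
            lab_i <- idx_lab[i]
            bond_i <- if (dir == 1) lab_i else ((lab_i - 2) %% n) + 1
            s <- paste0(s, toks[2 * lab_i - 1], toks[2 * bond_i])
          }
          if (is.null(best) || s < best) best <- s
        }
      }
      return(paste0("L1|R|", best))
    }
    # branch: center label, then parenthesized rays re-sorted
    m <- regmatches(body, regexec("^([^(]+)(.*)$", body))[[1]]
    rays <- regmatches(m[3], gregexpr("\\(([^)]*)\\)", m[3]))[[1]]
    rays <- sort(gsub("[()]", "", rays))
    paste0("L1|B|", m[2], paste0("(", rays, ")", collapse = ""))
  }
  for (smi in c("CC(=O)Oc1ccccc1C(=O)O", "c1ccncc1", "CC(C)(C)CO")) {
    g <- parse_structure(smi)
    l1 <- counts_as_named(count_fragments(g, 6, 1))
    l3 <- count_fragments(g, 6, 3)
    proj <- vapply(l3$key, recanonicalize, character(1))
    agg <- tapply(l3$count, proj, sum)
    agg <- stats::setNames(as.integer(agg), names(agg))
    expect_equal(sort_named(agg), l1, label = paste("refinement for", smi))
  }
})

test_that("increasing max_atoms never removes fragments or decreases counts", {
  g <- parse_structure("CC(C)Cc1ccc(cc1)C(C)C(=O)O")
  small <- counts_as_named(count_fragments(g, 4, 1:2))
  large <- counts_as_named(count_fragments(g, 8, 1:2))
  expect_true(all(names(small) %in% names(large)))
  expect_equal(large[names(small)], small)
  expect_gte(length(large), length(small))
})

test_that("the descriptor matrix is the catalog union with deterministic columns", {
  df <- tibble::tibble(id = c("methane", "ethane"), smiles = c("C", "CC"))
  dm <- build_descriptor_matrix(df, max_atoms = 8, levels = 1)
  expect_equal(colnames(dm$counts), c("L1|A|C", "L1|P|C-C"))
  expect_equal(unname(dm$counts), matrix(c(1L, 2L, 0L, 1L), nrow = 2))

  # single compound: every catalog column nonzero
  dm1 <- build_descriptor_matrix(df[2, ], max_atoms = 8, levels = 1)
  expect_true(all(colSums(dm1$counts > 0) >= 1))

  # duplicate rows produce identical count rows
  df2 <- tibble::tibble(id = c("x", "y"), smiles = c("CCO", "CCO"))
  dm2 <- build_descriptor_matrix(df2, max_atoms = 8, levels = 1:2)
  expect_equal(unname(dm2$counts[1, ]), unname(dm2$counts[2, ]))
})

test_that("unparseable compounds are excluded with a warning and reported", {
  df <- tibble::tibble(id = c("ok", "bad"), smiles = c("CCO", ")("))
  expect_warning(dm <- build_descriptor_matrix(df, max_atoms = 6, levels = 1),
                 "excluded")
  expect_equal(rownames(dm$counts), "ok")
  expect_equal(dm$rejects$id, "bad")
})

test_that("filter_rare drops fragments below the support threshold", {
  counts <- matrix(0L, nrow = 6, ncol = 3,
                   dimnames = list(paste0("c", 1:6), c("k1", "k2", "k3")))
  counts[1:4, 1] <- 1L   # present in exactly 4 compounds -> removed
  counts[1:5, 2] <- 2L   # present in exactly 5 compounds -> kept
  dm <- fragbb:::new_descriptor_matrix(counts)
  out <- filter_rare(dm, min_support = 5)
  expect_equal(colnames(out$counts), "k2")
  expect_equal(rownames(out$counts), rownames(counts))
})

test_that("descriptor matrices round trip through dense and sparse text formats", {
  df <- tibble::tibble(id = c("a", "b", "c"),
                       smiles = c("CCO", "CCN", "c1ccccc1"))
  dm <- build_descriptor_matrix(df, max_atoms = 4, levels = 1)
  for (fmt in c("tsv", "triplet")) {
    path <- tempfile(fileext = ".tsv")
    write_descriptor_matrix(dm, path, format = fmt)
    back <- read_descriptor_matrix(path, format = fmt)
    expect_equal(back$counts, dm$counts, label = fmt)
  }
})

test_that("key projection recovers the coarser-level keys a molecule generates", {
  # for any molecule, projecting its level-3 keys must land inside its
  # level-1 key set, and aggregated counts must match exactly
  for (smi in c("CC(=O)O", "Clc1ccccc1", "CC(C)(C)CO")) {
    g <- parse_structure(smi)
    l1 <- counts_as_named(count_fragments(g, 5, 1))
    l3 <- count_fragments(g, 5, 3)
    proj <- project_fragment_key(l3$key, level = 1)
    agg <- tapply(l3$count, proj, sum)
    expect_setequal(names(agg), names(l1))
    expect_equal(unname(agg[names(l1)]), unname(as.array(l1)),
                 label = paste("projected counts for", smi))
  }
  # level-2 projection of level-3 keys
  g <- parse_structure("Clc1ccccc1")
  l2 <- counts_as_named(count_fragments(g, 3, 2))
  l3 <- count_fragments(g, 3, 3)
  agg2 <- tapply(l3$count, project_fragment_key(l3$key, 2), sum)
  expect_setequal(names(agg2), names(l2))
  # keys at or below the target level pass through unchanged
  expect_equal(project_fragment_key("L1|A|C", 1), "L1|A|C")
  expect_true(is.na(project_fragment_key("garbage", 1)))
})

test_that("tidy() returns the nonzero cells in long form", {
  df <- tibble::tibble(id = c("m", "e"), smiles = c("C", "CC"))
  dm <- build_descriptor_matrix(df, max_atoms = 8, levels = 1)
  long <- tidy(dm)
  expect_equal(nrow(long), sum(dm$counts > 0))
  expect_equal(long$count[long$id == "e" & long$key == "L1|A|C"], 2L)
})
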