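# Shared fixtures, built lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# drug-like SMILES for round-trip / key stability checks
drug_smiles <- c(
  "CC(=O)Oc1ccccc1C(=O)O",            # aspirin
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O",       # ibuprofen
  "CN1CCC[C@H]1c1cccnc1",             # nicotine (stereo ignored)
  "Clc1ccccc1",                       # chlorobenzene
  "c1ccc2ccccc2c1",                   # naphthalene
  "CCN(CC)CC",                        # triethylamine
  "CC(=O)Nc1ccc(O)cc1",               # paracetamol
  "OCC(O)CO",                         # glycerol
  "c1ccoc1",                          # furan
  "c1ccsc1",                          # thiophene
  "c1ccncc1",                         # pyridine
  "CC(N)C(=O)O",                      # alanine
  "NC(=O)c1ccccc1",                   # benzamide
  "COc1ccccc1",                       # anisole
  "CC(C)(C)c1ccccc1",                 # tert-butylbenzene
  "FC(F)(F)c1ccccc1",                 # benzotrifluoride
  "O=S(=O)(N)c1ccccc1",               # benzenesulfonamide
  "CCOC(=O)C",                        # ethyl acetate
  "C1CCNCC1",                         # piperidine
  "CN(C)CCCl",                        # chloro amine
  "Cc1ccc(cc1)S(=O)(=O)N",            # tosylamide
  "OC(=O)CCC(=O)O"                    # succinic acid
)

# a small trained model shared by predictor / workflow tests
tiny_model <- function() {
  cached("tiny_model", function() {
    ds <- generate_dataset(synthetic_spec(n_compounds = 120, noise_sd = 0.15,
                                          max_atoms = 6, levels = 1:2,
                                          seed = 11))
    model <- train_logbb_model(
      ds$compounds, max_atoms = 6, levels = 1:2, min_support = 5,
      curation = NULL, dcv = dcv_spec(seed = 5),
      selection = list(method = "stepwise_pls", k = 25, score = "f_value"),
      hidden_ratios = 0.3, max_epochs = 300, patience = 15
    )
    list(model = model, data = ds)
  })
}

# Ensemble whose members each output a prescribed constant LogBB value;
# scalers are identity maps (fitted on 0/1) and every member reads the
# single fragment "L1|A|C".
constant_ensemble <- function(values) {
  members <- lapply(values, function(v) {
    spec <- network_spec(1, hidden_ratios = 1)
    list(
      network = structure(
        list(spec = spec,
             W = list(matrix(0, 1, 1), matrix(0, 1, 1)),
             b = list(0, v),
             training_log = NULL, stopped_epoch = 1L),
        class = "bbb_network"),
      x_scaler = fit_scaler(matrix(c(0, 1), ncol = 1), "range01"),
      y_scaler = fit_scaler(c(0, 1), "range01"),
      selected = "L1|A|C"
    )
  })
  structure(
    list(members = members, dcv = dcv_spec(), n_failed = 0L,
         catalog_keys = "L1|A|C",
         training = list(ids = character(0), y = numeric(0)),
         featurize = list(max_atoms = 3, levels = 1)),
    class = "bbb_ensemble"
  )
}

# Single-member ensemble that is exactly linear in the counts of `keys`:
# prediction = sum(w * count). Hidden layer kept in the positive SELU
# regime by a large bias, which the output bias cancels.
linear_ensemble <- function(keys, w, bias_shift = 20) {
  p <- length(keys)
  lambda <- 1.0507009873554805
  spec <- network_spec(p, hidden_ratios = 1)
  W1 <- diag(p)
  b1 <- rep(bias_shift, p)
  W2 <- matrix(w / lambda, ncol = 1)
  b2 <- -sum(w * bias_shift)
  net <- structure(
    list(spec = spec, W = list(W1, W2), b = list(b1, b2),
         training_log = NULL, stopped_epoch = 1L),
    class = "bbb_network")
  id_scaler <- fit_scaler(matrix(rep(c(0, 1), p), nrow = 2, byrow = FALSE),
                          "range01")
  member <- list(network = net, x_scaler = id_scaler,
                 y_scaler = fit_scaler(c(0, 1), "range01"),
                 selected = keys)
  structure(
    list(members = list(member), dcv = dcv_spec(), n_failed = 0L,
         catalog_keys = keys,
         training = list(ids = character(0), y = numeric(0)),
         featurize = list(max_atoms = 6, levels = 1:2)),
    class = "bbb_ensemble"
  )
}
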