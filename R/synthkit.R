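# Synthetic chemical library with known retention-time ground truth.
#
# Each class is a scaffold family carrying one distinctive functional group,
# chosen so the shipped taxonomy rules separate the families perfectly (this
# is what makes routing accuracy assertable). Members decorate the scaffold
# with alkyl chains (optionally branched, optionally halogen-terminated).
# Retention time is a linear function of two genuine molecular descriptors —
# a logP-type hydrophobicity surrogate and heavy-atom count — plus a
# class-level offset and Gaussian noise, clipped to the gradient window.
# Using computed descriptors (not the decoration grammar) as the signal
# forces the feature stage to actually recover it.

synth_families <- function() {
  list(
    benzoic_acids = list(
      superclass = "organic acids and derivatives",
      subclass = "benzoic acids and derivatives",
      build = function(r1, r2) {
        if (nzchar(r2)) paste0("OC(=O)c1ccc(", r1, ")c(", r2, ")c1")
        else paste0("OC(=O)c1ccc(", r1, ")cc1")
      }, r_pos = c("end", "end")
    ),
    anilines = list(
      superclass = "organic nitrogen compounds",
      subclass = "anilines",
      build = function(r1, r2) {
        if (nzchar(r2)) paste0("Nc1ccc(", r1, ")c(", r2, ")c1")
        else paste0("Nc1ccc(", r1, ")cc1")
      }, r_pos = c("end", "end")
    ),
    sulfonamides = list(
      superclass = "organosulfur compounds",
      subclass = "sulfonamides",
      build = function(r1, r2) {
        if (nzchar(r2)) paste0("NS(=O)(=O)c1ccc(", r1, ")c(", r2, ")c1")
        else paste0("NS(=O)(=O)c1ccc(", r1, ")cc1")
      }, r_pos = c("end", "end")
    ),
    pyridines = list(
      superclass = "organoheterocyclic compounds",
      subclass = "pyridines and derivatives",
      build = function(r1, r2) {
        if (nzchar(r2)) paste0(r1, "c1ccnc(", r2, ")c1")
        else paste0(r1, "c1ccncc1")
      }, r_pos = c("start", "end")
    ),
    esters = list(
      superclass = "organic oxygen compounds",
      subclass = "carboxylic acid esters",
      build = function(r1, r2) {
        if (!nzchar(r2)) r2 <- "C"
        paste0(r1, "C(=O)O", r2)
      }, r_pos = c("start", "end")
    ),
    ketones = list(
      superclass = "organic oxygen compounds",
      subclass = "ketones",
      build = function(r1, r2) {
        if (!nzchar(r2)) r2 <- "C"
        paste0(r1, "C(=O)", r2)
      }, r_pos = c("start", "end")
    ),
    haloalkanes = list(
      superclass = "organohalogen compounds",
      subclass = "halogenated hydrocarbons",
      build = function(r1, r2) {
        # r1 carries the mandatory halogen at the start; r2 optional tail
        paste0(r1, if (nzchar(r2)) r2 else "")
      }, r_pos = c("start", "end")
    ),
    alkylbenzenes = list(
      superclass = "benzenoids",
      subclass = "benzene and substituted derivatives",
      build = function(r1, r2) {
        if (nzchar(r2)) paste0(r1, "c1ccc(", r2, ")cc1")
        else paste0(r1, "c1ccccc1")
      }, r_pos = c("start", "end")
    )
  )
}

# Alkyl substituent grammar: chain of `len` carbons, optional methyl branch,
# optional halogen placed at the free end ("start" when the chain is pasted
# to the left of the scaffold, "end" when inside a ring branch).
synth_chain <- function(len, branch = FALSE, halo = "", pos = "end") {
  if (len <= 0) return("")
  body <- if (branch && len >= 2) {
    paste0("C(C)", strrep("C", len - 1))
  } else {
    strrep("C", len)
  }
  if (!nzchar(halo)) return(body)
  if (pos == "start") paste0(halo, body) else paste0(body, halo)
}

#' Synthetic-library configuration
#'
#' Defaults describe a mid-size class-structured library on a ~30-minute
#' gradient: retention times in the tens-to-1700 s window, 10 s measurement
#' noise, and 300 s of between-class offset spread.
#'
#' @param n_classes number of scaffold families, 2..8 (default 6).
#' @param per_class molecules per family (default 200, >= 20).
#' @param noise_sd Gaussian noise sd in seconds (default 10).
#' @param rt_floor,rt_ceiling gradient clip window in seconds (60, 1700).
#' @param class_offset_spread total spread of class offsets in seconds (300).
#' @param seed integer seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_classes = 6L, per_class = 200L, noise_sd = 10,
                         rt_floor = 60, rt_ceiling = 1700,
                         class_offset_spread = 300, seed = 1L) {
  stopifnot(n_classes >= 2, n_classes <= 8, per_class >= 20, noise_sd >= 0,
            rt_floor < rt_ceiling)
  structure(
    list(
      n_classes = as.integer(n_classes), per_class = as.integer(per_class),
      noise_sd = noise_sd, rt_floor = rt_floor, rt_ceiling = rt_ceiling,
      class_offset_spread = class_offset_spread, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Generate a synthetic chemical library with known retention times
#'
#' @param cfg a [synth_config()].
#' @return list with `data` (an [rt_dataset] carrying extra columns
#'   `gen_superclass`, `gen_subclass`: the generating family's taxonomy
#'   class) and `truth` (list: `rt_noiseless`, `noise`, `offsets`, `coef`,
#'   `clipped`); `data$rt` equals `clip(rt_noiseless + noise)` exactly.
#' @export
generate_library <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  fams <- synth_families()[seq_len(cfg$n_classes)]
  offsets <- if (cfg$n_classes > 1) {
    seq(-cfg$class_offset_spread / 2, cfg$class_offset_spread / 2,
        length.out = cfg$n_classes)
  } else {
    0
  }
  names(offsets) <- names(fams)

  rows <- list()
  for (ci in seq_along(fams)) {
    fam <- fams[[ci]]
    fam_name <- names(fams)[ci]
    smiles <- with_seed(derive_seed(cfg$seed, paste0("class:", fam_name)), {
      seen <- character(0)
      out <- character(0)
      rounds <- 0L
      force_halo <- fam_name == "haloalkanes"
      halos <- c("", "", "", "F", "Cl")
      # propose decorations in batches so canonicalization is one backend
      # call per round rather than one per molecule
      while (length(out) < cfg$per_class && rounds < 30L) {
        rounds <- rounds + 1L
        n_prop <- 2L * cfg$per_class
        prop <- vapply(seq_len(n_prop), function(i) {
          r1 <- synth_chain(
            len = sample(2:8, 1), branch = stats::runif(1) < 0.4,
            halo = if (force_halo) sample(c("F", "Cl", "Br"), 1) else sample(halos, 1),
            pos = fam$r_pos[1]
          )
          r2 <- if (stats::runif(1) < 0.6) {
            synth_chain(
              len = sample(0:6, 1), branch = stats::runif(1) < 0.3,
              halo = sample(c("", "F", "Cl"), 1),
              pos = fam$r_pos[2]
            )
          } else {
            ""
          }
          fam$build(r1, r2)
        }, character(1))
        can <- chem_canonicalize(prop)
        ok <- !is.na(can) & !duplicated(can) & !(can %in% seen)
        seen <- c(seen, can[ok])
        out <- c(out, prop[ok])
      }
      utils::head(out, cfg$per_class)
    })
    if (length(smiles) < cfg$per_class) {
      stopf("family '%s': only %d distinct molecules generated (wanted %d)",
            fam_name, length(smiles), cfg$per_class)
    }
    rows[[ci]] <- data.frame(
      id = sprintf("c%d_m%03d", ci, seq_along(smiles)),
      smiles = smiles,
      family = fam_name,
      gen_superclass = fam$superclass,
      gen_subclass = fam$subclass,
      stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, rows)

  tab <- rt_dataset(id = df$id, smiles = df$smiles)
  stopifnot(nrow(tab) == nrow(df)) # grammar guarantees validity
  desc <- chem_descriptors(tab$smiles_canonical)
  logp <- desc[, "MolLogP"]
  heavy <- desc[, "HeavyAtomCount"]
  coef <- c(a = 100, b = 20, base = 150)
  rt_noiseless <- coef["a"] * logp + coef["b"] * heavy + coef["base"] +
    offsets[df$family]
  noise <- with_seed(derive_seed(cfg$seed, "noise"),
                     stats::rnorm(nrow(df), 0, cfg$noise_sd))
  rt_raw <- rt_noiseless + noise
  rt <- pmin(pmax(rt_raw, cfg$rt_floor), cfg$rt_ceiling)
  tab$rt <- as.numeric(rt)
  tab$gen_superclass <- df$gen_superclass
  tab$gen_subclass <- df$gen_subclass
  list(
    data = tab,
    truth = list(
      rt_noiseless = as.numeric(rt_noiseless),
      noise = noise,
      offsets = offsets,
      coef = coef,
      clipped = rt_raw != rt
    )
  )
}

#' Build a deliberately data-sparse training regime
#'
#' Emulates the sparsity that per-class partitioning induces: a small
#' training split per class plus a large labeled pool sharing the same
#' scaffolds, so similarity-thresholded recruitment has true signal to add.
#' Train, validation, test and pool are disjoint by canonical SMILES.
#'
#' @param cfg a [synth_config()]; `per_class` must cover
#'   `n_train + n_val + n_test` plus a non-empty pool.
#' @param n_train,n_val,n_test per-class split sizes (defaults 15/10/10;
#'   the remainder of each class becomes pool).
#' @return list with `train`, `val`, `test`, `pool` ([rt_dataset]s) and
#'   `truth`.
#' @export
make_sparse_regime <- function(cfg = synth_config(n_classes = 4L, per_class = 90L),
                               n_train = 15L, n_val = 10L, n_test = 10L) {
  need <- n_train + n_val + n_test
  if (cfg$per_class <= need) {
    stopf("per_class (%d) must exceed n_train+n_val+n_test (%d) to leave a pool",
          cfg$per_class, need)
  }
  lib <- generate_library(cfg)
  tab <- lib$data
  folds <- c(
    rep("train", n_train), rep("val", n_val), rep("test", n_test),
    rep("pool", cfg$per_class - need)
  )
  fold <- character(nrow(tab))
  for (fam in unique(tab$gen_subclass)) {
    idx <- which(tab$gen_subclass == fam)
    perm <- with_seed(derive_seed(cfg$seed, paste0("sparse:", fam)),
                      sample(idx))
    fold[perm] <- folds[seq_along(perm)]
  }
  pick <- function(f) as_rt_dataset(tab[fold == f, , drop = FALSE])
  list(
    train = pick("train"), val = pick("val"), test = pick("test"),
    pool = pick("pool"), truth = lib$truth
  )
}
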