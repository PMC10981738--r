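#' Specification of a synthetic benchmark fixture
#'
#' Describes a planted SCOP-style dataset: a fold > superfamily > family
#' hierarchy, per-fold prototype sequences mutated into members, pooled
#' embeddings drawn around per-fold centroids, clan-structured domain
#' annotations with a power-law (long-tailed) clan-size distribution, and
#' TM-score labels generated from a planted bilinear model.  Every draw is
#' fixed by `seed`.
#'
#' Defaults define the package's reference study conditions: 100 proteins
#' in 5 folds x 2 superfamilies x 2 families, 32-dimensional embeddings
#' with within-fold noise 0.25, label noise 0.02, 8 clans with tail
#' exponent 2.5, a 5% no-domain fraction (the share of queries that scan
#' no domain in real benchmarks is of this order), and a 15% point-mutation
#' rate between same-fold sequences.
#'
#' @param n_proteins number of proteins.
#' @param n_folds,superfamilies_per_fold,families_per_superfamily planted
#'   hierarchy shape.
#' @param seq_length length-2 integer range of prototype sequence lengths.
#' @param dim embedding dimension `d` (>= 21 for the mock encoder).
#' @param sigma_emb sd of pooled-embedding noise around the fold centroid.
#' @param sigma_tm sd of Gaussian noise on TM-score labels.
#' @param n_clans number of Pfam-style clans.
#' @param tail_exponent power-law exponent of clan popularity; steeper
#'   values concentrate folds into the largest clans, reproducing the
#'   long-tailed cluster-size distribution of real clan annotations.
#' @param mut_rate per-position substitution rate applied to the fold
#'   prototype when emitting a member sequence.
#' @param frac_no_domain fraction of proteins with no domain annotation.
#' @param frac_second_family fraction of annotated proteins carrying a
#'   second family from the same fold.
#' @param frac_unmapped fraction of families absent from the clan map
#'   (they fall back to acting as their own clan).
#' @param residue_noise_sd jitter of the mock per-residue profiles.
#' @param seed integer seed fixing every draw.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_proteins = 100L, n_folds = 5L,
                         superfamilies_per_fold = 2L,
                         families_per_superfamily = 2L,
                         seq_length = c(50L, 120L), dim = 32L,
                         sigma_emb = 0.25, sigma_tm = 0.02,
                         n_clans = 8L, tail_exponent = 2.5,
                         mut_rate = 0.15, frac_no_domain = 0.05,
                         frac_second_family = 0.2, frac_unmapped = 0.1,
                         residue_noise_sd = 0.05, seed = 1L) {
  n_families <- n_folds * superfamilies_per_fold * families_per_superfamily
  if (n_proteins < n_families) {
    stop_("infeasible hierarchy: %d proteins cannot populate %d families",
          n_proteins, n_families)
  }
  stopifnot(length(seq_length) == 2L, seq_length[1] >= 1,
            seq_length[2] >= seq_length[1],
            sigma_emb >= 0, sigma_tm >= 0, n_clans >= 1,
            tail_exponent > 0, mut_rate >= 0, mut_rate <= 1)
  structure(as.list(environment())[c(
    "n_proteins", "n_folds", "superfamilies_per_fold",
    "families_per_superfamily", "seq_length", "dim", "sigma_emb",
    "sigma_tm", "n_clans", "tail_exponent", "mut_rate", "frac_no_domain",
    "frac_second_family", "frac_unmapped", "residue_noise_sd", "seed")],
    class = "fixture_spec")
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat(sprintf("<fixture_spec> %d proteins, %d folds x %d sf x %d fam, d = %d, seed %d\n",
              x$n_proteins, x$n_folds, x$superfamilies_per_fold,
              x$families_per_superfamily, x$dim, x$seed))
  invisible(x)
}

#' Generate a complete synthetic dataset
#'
#' Produces every input the pipeline consumes, with the statistical
#' structure the method assumes:
#' \itemize{
#'   \item protein records: each fold has a random prototype sequence;
#'     members are point-mutated copies, so same-fold pairs are genuinely
#'     alignable and cross-fold pairs are not;
#'   \item fold labels: balanced assignment of proteins to the planted
#'     family/superfamily/fold hierarchy;
#'   \item pooled embeddings: fold centroid plus isotropic Gaussian noise
#'     (`sigma_emb`), so embedding similarity tracks fold identity;
#'   \item per-residue embeddings: deterministic context-free mock
#'     encoder profiles;
#'   \item annotations and clan map: one family accession per protein
#'     (optionally a second same-fold family); families map to per-fold
#'     clans whose popularity follows a power law, yielding the
#'     long-tailed clan-cluster distribution seen in real annotations; a
#'     fraction of proteins carries no domain and a fraction of families
#'     no clan.
#' }
#'
#' @param spec a [fixture_spec()].
#' @return list with elements `records`, `fold_labels`, `annotations`,
#'   `clan_map`, `store` (an [embedding_store()] with planted pooled
#'   vectors and mock per-residue matrices), and `centroids`.
#' @export
make_dataset <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    n <- spec$n_proteins
    ids <- sprintf("prot%04d", seq_len(n))

    # balanced hierarchy assignment: protein i -> family (i mod F)
    n_sf <- spec$n_folds * spec$superfamilies_per_fold
    n_fam <- n_sf * spec$families_per_superfamily
    fam_idx <- (seq_len(n) - 1L) %% n_fam + 1L
    sf_idx <- (fam_idx - 1L) %/% spec$families_per_superfamily + 1L
    fold_idx <- (sf_idx - 1L) %/% spec$superfamilies_per_fold + 1L
    fold_labels <- data.frame(
      id = ids,
      family = sprintf("FAM%03d", fam_idx),
      superfamily = sprintf("SF%03d", sf_idx),
      fold = sprintf("FOLD%03d", fold_idx),
      stringsAsFactors = FALSE)
    validate_fold_labels(fold_labels)

    # sequences: fold prototype + per-position substitutions
    aa20 <- setdiff(AA_ALPHABET, "X")
    proto_len <- spec$seq_length[1] - 1L +
      sample.int(spec$seq_length[2] - spec$seq_length[1] + 1L,
                 spec$n_folds, replace = TRUE)
    protos <- lapply(proto_len, function(L) sample(aa20, L, replace = TRUE))
    seqs <- vapply(seq_len(n), function(i) {
      p <- protos[[fold_idx[i]]]
      mut <- runif(length(p)) < spec$mut_rate
      p[mut] <- sample(aa20, sum(mut), replace = TRUE)
      paste0(p, collapse = "")
    }, character(1))
    records <- data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)

    # pooled embeddings: fold centroid + noise
    centroids <- matrix(rnorm(spec$n_folds * spec$dim), spec$n_folds, spec$dim)
    pooled <- lapply(seq_len(n), function(i) {
      centroids[fold_idx[i], ] + rnorm(spec$dim, sd = spec$sigma_emb)
    })
    names(pooled) <- ids

    # per-residue embeddings from the deterministic mock encoder
    enc <- encoder_spec("mock", dim = spec$dim,
                        seed = derive_seed(spec$seed, "encoder"),
                        noise_sd = spec$residue_noise_sd)
    per_res <- lapply(setNames(seqs, ids), encode_protein, spec = enc)
    store <- embedding_store(per_residue = per_res, pooled = pooled)

    # clans: per-fold clans drawn from a power-law popularity distribution
    clan_pop <- (seq_len(spec$n_clans))^(-spec$tail_exponent)
    fold_clans <- lapply(seq_len(spec$n_folds), function(f) {
      k <- sample(1:2, 1L)
      sort(unique(sample.int(spec$n_clans, k, replace = TRUE,
                             prob = clan_pop)))
    })
    fam_ids <- sprintf("PF%05d", seq_len(n_fam))
    fam_fold <- (((seq_len(n_fam) - 1L) %/% spec$families_per_superfamily) %/%
                   spec$superfamilies_per_fold) + 1L
    fam_clan <- vapply(seq_len(n_fam), function(f) {
      cl <- fold_clans[[fam_fold[f]]]
      cl[(f - 1L) %% length(cl) + 1L]
    }, integer(1))
    clan_map <- setNames(sprintf("CL%04d", fam_clan), fam_ids)
    unmapped <- runif(n_fam) < spec$frac_unmapped
    clan_map <- clan_map[!unmapped]

    # annotations: own family, sometimes a second family from the fold,
    # and a no-domain fraction
    no_dom <- runif(n) < spec$frac_no_domain
    annotations <- lapply(seq_len(n), function(i) {
      if (no_dom[i]) return(character())
      fams <- fam_ids[fam_idx[i]]
      if (runif(1) < spec$frac_second_family) {
        same_fold <- which(fam_fold == fold_idx[i])
        extra <- fam_ids[same_fold[sample.int(length(same_fold), 1L)]]
        fams <- sort(unique(c(fams, extra)))
      }
      fams
    })
    names(annotations) <- ids

    list(records = records, fold_labels = fold_labels,
         annotations = annotations, clan_map = clan_map,
         store = store, centroids = centroids)
  })
}

#' Generate TM-score training labels from a planted bilinear model
#'
#' Samples random query-target pairs from a dataset and labels each with
#' `clamp01(z1' W* z2 + shift * same_fold + noise)`, where `W*` is a
#' planted bilinear model (default: identity scaled to `1/(2d)`, under
#' which same-fold pairs score around 0.5 and cross-fold pairs near 0).
#' Optional balancing resamples the table so a stated fraction of labels
#' exceeds 0.5, mirroring the dataset-level undersampling used to enrich
#' positive pairs when training against real structure labels.
#'
#' @param dataset a dataset from [make_dataset()].
#' @param n_pairs number of labeled pairs to draw.
#' @param planted_W planted `d x d` matrix (default scaled identity).
#' @param sigma_tm label noise sd (default: the generating spec is not
#'   known here, so 0.02).
#' @param fold_shift additive mean shift for same-fold pairs (default 0;
#'   the planted centroids already make same-fold labels larger).
#' @param balance_fraction if non-NULL, resample so this fraction of
#'   labels is > 0.5.
#' @param seed integer seed.
#' @return data.frame with columns `query`, `target`, `tm_score`, and
#'   attribute `planted_W`.
#' @export
make_training_pairs <- function(dataset, n_pairs = 2000L, planted_W = NULL,
                                sigma_tm = 0.02, fold_shift = 0,
                                balance_fraction = NULL, seed = 1L) {
  ids <- dataset$records$id
  d <- dataset$store$dim
  if (is.null(planted_W)) planted_W <- diag(d) / (2 * d)
  fold_of <- setNames(dataset$fold_labels$fold, dataset$fold_labels$id)
  with_seed(seed, {
    qi <- sample(ids, n_pairs, replace = TRUE)
    ti <- sample(ids, n_pairs, replace = TRUE)
    Z1 <- pooled_matrix(dataset$store, qi)
    Z2 <- pooled_matrix(dataset$store, ti)
    raw <- rowSums((Z1 %*% planted_W) * Z2)
    raw <- raw + fold_shift * (fold_of[qi] == fold_of[ti])
    tm <- pmin(pmax(raw + rnorm(n_pairs, sd = sigma_tm), 0), 1)
    pairs <- data.frame(query = qi, target = ti, tm_score = unname(tm),
                        stringsAsFactors = FALSE)
    if (!is.null(balance_fraction)) {
      pos <- which(pairs$tm_score > 0.5)
      neg <- which(pairs$tm_score <= 0.5)
      if (length(pos) == 0L || length(neg) == 0L) {
        stop_("cannot balance: one label class is empty")
      }
      n_pos <- round(balance_fraction * n_pairs)
      resample <- function(x, size) {
        x[sample.int(length(x), size, replace = size > length(x))]
      }
      keep <- c(resample(pos, n_pos), resample(neg, n_pairs - n_pos))
      pairs <- pairs[sample(keep), , drop = FALSE]
      rownames(pairs) <- NULL
    }
    attr(pairs, "planted_W") <- planted_W
    pairs
  })
}
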