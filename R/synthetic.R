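#' Specification for a synthetic methylation cohort
#'
#' Describes a simulated cohort: class sizes (imbalance allowed), probe
#' count, how many probes carry class signal, how far informative probes are
#' shifted, how tight the Beta noise is, and the missing-at-random rate.
#' Beta values are parameterised by (mean, concentration): a draw at mean
#' `m` with concentration `c` is `Beta(m * c, (1 - m) * c)`, so larger
#' concentration means tighter values around the mean.
#'
#' Defaults emulate a small cfDNA-style cohort: 3 classes of 20 samples,
#' 200 probes of which 10 per class are informative with an effect size
#' (mean-shift) of 0.3, concentration 50, and 10% missingness — the
#' missingness regime of array cohorts after detection-P masking typically
#' falls in the 10-30% band.
#'
#' @param n_classes Number of classes.
#' @param samples_per_class Integer vector (recycled) of per-class sample
#'   counts; unequal values give an imbalanced cohort.
#' @param n_probes Total probe count.
#' @param n_informative_per_class Informative probes per class (disjoint
#'   across classes).
#' @param effect_size Mean beta shift at informative probes, in `(0, 0.5]`.
#' @param beta_concentration Beta-distribution concentration (noise
#'   tightness).
#' @param missing_rate Missing-completely-at-random rate in `[0, 1)`.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `synthetic_cohort_spec` list.
#' @export
synthetic_cohort_spec <- function(n_classes = 3, samples_per_class = 20,
                                  n_probes = 200, n_informative_per_class = 10,
                                  effect_size = 0.3, beta_concentration = 50,
                                  missing_rate = 0.1, seed = 1) {
  samples_per_class <- rep_len(as.integer(samples_per_class), n_classes)
  if (n_classes < 1 || any(samples_per_class < 1)) {
    abort_mt("Need at least one class and one sample per class.", "spec_error")
  }
  if (n_informative_per_class * n_classes > n_probes) {
    abort_mt("Informative probes (n_informative_per_class * n_classes) exceed n_probes.",
             "spec_error")
  }
  if (effect_size <= 0 || effect_size > 0.5) {
    abort_mt("effect_size must lie in (0, 0.5].", "spec_error")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort_mt("missing_rate must lie in [0, 1).", "spec_error")
  }
  if (beta_concentration <= 0) {
    abort_mt("beta_concentration must be positive.", "spec_error")
  }
  structure(
    list(
      n_classes = n_classes, samples_per_class = samples_per_class,
      n_probes = n_probes, n_informative_per_class = n_informative_per_class,
      effect_size = effect_size, beta_concentration = beta_concentration,
      missing_rate = missing_rate, seed = as.integer(seed)
    ),
    class = "synthetic_cohort_spec"
  )
}

#' Generate a labelled synthetic methylation cohort
#'
#' Background probes have mean beta 0.5; each class's informative probes are
#' shifted by +/- `effect_size` (direction alternating per probe, so classes
#' show both hyper- and hypomethylation). Values are Beta-distributed with
#' the spec's concentration and clipped to `[0, 1]` by construction; missing
#' entries are inserted completely at random at `missing_rate`.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param domain_tag Domain tag for the cohort.
#' @param informative_probes Optional list (per class) of probe indices to
#'   use as informative sites; defaults to a seeded random disjoint
#'   assignment. Used by [generate_domain_pair()] to share sites between
#'   domains.
#' @param missing_rate_by_class Optional numeric vector (one rate per
#'   class, recycled) overriding the spec's global `missing_rate`:
#'   class-biased missingness, e.g. to exercise the per-class probe filter
#'   with probes that fail only in one class. Default `NULL` keeps
#'   missingness completely at random at the spec's rate.
#' @param informative_direction Direction of the planted shift:
#'   `"alternating"` (default; odd sites hyper-, even sites hypomethylated),
#'   `"hyper"` (all up — promoter-hypermethylation-style markers), or
#'   `"hypo"` (all down). Fused features scale with beta, so hypomethylated
#'   markers carry low-magnitude rows; constructions probing
#'   gradient-times-input attribution use `"hyper"`.
#' @param id_prefix Prefix for sample ids (domain pairs need disjoint ids).
#' @return List with `cohort` (a [methylation_cohort()]) and `planted`, a
#'   tibble mapping class to its informative probe ids and shift direction.
#' @export
generate_cohort <- function(spec, domain_tag = "target",
                            informative_probes = NULL,
                            missing_rate_by_class = NULL,
                            informative_direction = c("alternating", "hyper", "hypo"),
                            id_prefix = "S") {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  informative_direction <- match.arg(informative_direction)
  with_seed(spec$seed, {
    n <- sum(spec$samples_per_class)
    p <- spec$n_probes
    classes <- paste0("class", seq_len(spec$n_classes))
    labels <- rep(classes, spec$samples_per_class)
    probe_names <- sprintf("cg%06d", seq_len(p))
    if (is.null(informative_probes)) {
      pool <- sample.int(p, spec$n_informative_per_class * spec$n_classes)
      informative_probes <- split(
        pool, rep(seq_len(spec$n_classes), each = spec$n_informative_per_class)
      )
    }
    mu <- matrix(0.5, n, p)
    planted <- list()
    for (ci in seq_len(spec$n_classes)) {
      idx <- informative_probes[[ci]]
      dirs <- switch(informative_direction,
        alternating = ifelse(seq_along(idx) %% 2 == 1, 1, -1),
        hyper = rep(1, length(idx)),
        hypo = rep(-1, length(idx))
      )
      rows <- labels == classes[ci]
      for (j in seq_along(idx)) {
        mu[rows, idx[j]] <- 0.5 + dirs[j] * spec$effect_size
      }
      planted[[ci]] <- tibble::tibble(
        class = classes[ci], probe_id = probe_names[idx], direction = dirs
      )
    }
    conc <- spec$beta_concentration
    beta <- matrix(
      stats::rbeta(n * p, shape1 = mu * conc, shape2 = (1 - mu) * conc), n, p
    )
    if (!is.null(missing_rate_by_class)) {
      rates <- rep_len(missing_rate_by_class, spec$n_classes)
      if (any(rates < 0 | rates >= 1)) {
        abort_mt("Per-class missing rates must lie in [0, 1).", "spec_error")
      }
      row_rate <- rates[match(labels, classes)]
      beta[stats::runif(n * p) < row_rate] <- NA_real_
    } else if (spec$missing_rate > 0) {
      beta[stats::runif(n * p) < spec$missing_rate] <- NA_real_
    }
    rownames(beta) <- sprintf("%s%03d", id_prefix, seq_len(n))
    colnames(beta) <- probe_names
    list(
      cohort = methylation_cohort(beta, labels = stats::setNames(labels, rownames(beta)),
                                  domain_tag = domain_tag),
      planted = dplyr::bind_rows(planted),
      informative_probes = informative_probes
    )
  })
}

#' Generate a source/target domain pair
#'
#' Emulates the bulk-to-cfDNA transfer setting: a larger, class-rich source
#' cohort and a smaller target cohort whose classes reuse a fraction of the
#' source's informative probes, typically with an attenuated effect size
#' (tumour signal in cfDNA is diluted by background DNA). Target class `i`
#' reuses `shared_informative_fraction` of source class `i`'s informative
#' sites; the remainder are freshly drawn sites.
#'
#' @param source_spec,target_spec [synthetic_cohort_spec()]s. Defaults:
#'   source 6 classes x 40 samples, effect 0.3; target 3 classes x 20
#'   samples, effect 0.18 (attenuated).
#' @param shared_informative_fraction Fraction in `[0, 1]` of each target
#'   class's informative probes taken from the matching source class.
#' @return List with `source` and `target` generation results (each as from
#'   [generate_cohort()]).
#' @export
generate_domain_pair <- function(
    source_spec = synthetic_cohort_spec(
      n_classes = 6, samples_per_class = 40, n_probes = 200,
      n_informative_per_class = 10, effect_size = 0.3, missing_rate = 0.1,
      seed = 1
    ),
    target_spec = synthetic_cohort_spec(
      n_classes = 3, samples_per_class = 20, n_probes = 200,
      n_informative_per_class = 10, effect_size = 0.18, missing_rate = 0.1,
      seed = 2
    ),
    shared_informative_fraction = 0.8) {
  if (source_spec$n_probes != target_spec$n_probes) {
    abort_mt("Source and target must share a probe panel (equal n_probes).",
             "spec_error")
  }
  if (shared_informative_fraction < 0 || shared_informative_fraction > 1) {
    abort_mt("shared_informative_fraction must lie in [0, 1].", "spec_error")
  }
  if (target_spec$n_classes > source_spec$n_classes) {
    abort_mt("Target cannot have more classes than the source.", "spec_error")
  }
  src <- generate_cohort(source_spec, domain_tag = "source", id_prefix = "SRC")
  tgt_informative <- with_seed(derive_seed(target_spec$seed, "shared_sites"), {
    n_inf <- target_spec$n_informative_per_class
    n_shared <- round(shared_informative_fraction * n_inf)
    used <- unlist(src$informative_probes)
    lapply(seq_len(target_spec$n_classes), function(ci) {
      shared <- src$informative_probes[[ci]][seq_len(n_shared)]
      n_new <- n_inf - n_shared
      new <- if (n_new > 0) {
        sample(setdiff(seq_len(target_spec$n_probes), used), n_new)
      } else {
        integer(0)
      }
      used <<- c(used, new)
      c(shared, new)
    })
  })
  tgt <- generate_cohort(target_spec, domain_tag = "target",
                         informative_probes = tgt_informative, id_prefix = "TGT")
  list(source = src, target = tgt)
}

#' Generate a toy genome and probe manifest
#'
#' Builds a random single-chromosome genome and a manifest of probe
#' positions spaced so that every 50-bp flank window (25 bases either side)
#' lies inside the chromosome. Strands alternate and gene symbols are
#' assigned round-robin so probe-to-gene mapping is exercisable.
#'
#' @param n_probes Number of probes.
#' @param chrom_length Chromosome length in bases.
#' @param seed Integer seed.
#' @param n_genes Number of distinct gene symbols to cycle through.
#' @return List with `genome` (a named [Biostrings::DNAStringSet]) and
#'   `manifest` (tibble: probe_id, chrom, pos, strand, genes).
#' @export
generate_toy_genome_and_manifest <- function(n_probes, chrom_length = 10000,
                                             seed = 1, n_genes = 10) {
  usable <- chrom_length - 49 # positions with both flanks inside
  if (usable < n_probes) {
    abort_mt("Chromosome too short for that many probes with 25-bp flanks.",
             "layout_error")
  }
  with_seed(seed, {
    genome_chars <- sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE)
    genome <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
    names(genome) <- "chr1"
    pos <- sort(sample(seq(26L, chrom_length - 24L), n_probes))
    manifest <- tibble::tibble(
      probe_id = sprintf("cg%06d", seq_len(n_probes)),
      chrom = "chr1",
      pos = pos,
      strand = rep_len(c("+", "-"), n_probes),
      genes = paste0("GENE", (seq_len(n_probes) - 1L) %% n_genes + 1L)
    )
    list(genome = genome, manifest = manifest)
  })
}
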