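#' Signed fold change between two positive group means
#'
#' Increases are reported as `alt/ref`, decreases as `-(ref/alt)`, so the
#' magnitude is always at least 1 and the sign gives the direction
#' (positive means up in the alternative group).
#'
#' @param ref_mean,alt_mean Positive group means (reference, e.g. WT, and
#'   alternative, e.g. MUT). Vectorised.
#' @return Signed fold change(s), |fold| >= 1.
#' @export
signed_fold <- function(ref_mean, alt_mean) {
  if (any(ref_mean <= 0) || any(alt_mean <= 0)) {
    stop("signed fold change requires positive means", call. = FALSE)
  }
  ifelse(alt_mean >= ref_mean, alt_mean / ref_mean, -(ref_mean / alt_mean))
}

#' Flag an inconsistent replicate among three
#'
#' Reconstruction of the two-of-three consistency rule used when one array
#' replicate disagrees with the other two: replicate i is flagged when
#' |value_i - median| exceeds `f_max` times max(median, eps). At most one
#' replicate (the most deviant) is flagged; means and SDs are then computed
#' over the kept values.
#'
#' @param values Numeric vector of exactly 3 replicate values.
#' @param f_max Fractional deviation threshold (default 0.5).
#' @param eps Floor protecting near-zero medians (default 1e-6).
#' @return List with `kept` (values retained), `flagged` (index in 1..3 or
#'   `NA`), `mean`, `sd`.
#' @export
replicate_filter <- function(values, f_max = 0.5, eps = 1e-6) {
  if (length(values) != 3L || anyNA(values)) {
    stop("replicate_filter expects exactly 3 non-missing values",
         call. = FALSE)
  }
  med <- stats::median(values)
  dev <- abs(values - med)
  lim <- f_max * max(med, eps)
  flagged <- NA_integer_
  if (any(dev > lim)) flagged <- which.max(dev)
  kept <- if (is.na(flagged)) values else values[-flagged]
  list(kept = kept, flagged = flagged, mean = mean(kept),
       sd = stats::sd(kept))
}

#' Simulate replicated expression values per genotype
#'
#' Each replicate is the group mean plus Gaussian noise; with probability
#' `outlier_rate` one replicate per gene-by-genotype cell is corrupted by a
#' multiplicative factor drawn outside \[0.5, 2\] (uniform on
#' \[2.5, 4\] or \[0.1, 0.4\]), emulating an inconsistent array.
#'
#' @param spec Data frame with columns `gene`, `category`, `wt_mean`,
#'   `het_mean`, `mut_mean` and optionally `noise_sd` (default 5% of the
#'   mean).
#' @param n_replicates Replicates per genotype (default 3).
#' @param outlier_rate Corruption probability per gene x genotype.
#' @param seed Integer seed.
#' @return Long data frame `gene,category,genotype,replicate,value` with
#'   attribute `corrupted` (data frame of gene/genotype/replicate actually
#'   corrupted).
#' @export
simulate_expression <- function(spec, n_replicates = 3, outlier_rate = 0,
                                seed = 1L) {
  need <- c("gene", "wt_mean", "het_mean", "mut_mean")
  if (!all(need %in% names(spec))) {
    stop("spec needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(spec$wt_mean < 0 | spec$het_mean < 0 | spec$mut_mean < 0)) {
    stop("group means must be >= 0", call. = FALSE)
  }
  if (n_replicates < 2) stop("n_replicates must be >= 2", call. = FALSE)
  if (!"category" %in% names(spec)) spec$category <- "unassigned"
  genotypes <- c(WT = "wt_mean", HET = "het_mean", MUT = "mut_mean")

  with_seed(seed, {
    rows <- list(); corrupted <- list()
    for (g in seq_len(nrow(spec))) {
      nsd <- if ("noise_sd" %in% names(spec)) spec$noise_sd[g] else NA_real_
      for (geno in names(genotypes)) {
        mu <- spec[[genotypes[[geno]]]][g]
        s <- if (is.na(nsd)) 0.05 * mu else nsd
        v <- mu + stats::rnorm(n_replicates, 0, s)
        v <- pmax(v, 0)
        if (outlier_rate > 0 && stats::runif(1) < outlier_rate) {
          idx <- sample.int(n_replicates, 1)
          up <- stats::runif(1) < 0.5
          fac <- if (up) stats::runif(1, 2.5, 4) else stats::runif(1, 0.1, 0.4)
          v[idx] <- v[idx] * fac
          corrupted[[length(corrupted) + 1L]] <-
            data.frame(gene = spec$gene[g], genotype = geno,
                       replicate = idx)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          gene = spec$gene[g], category = spec$category[g], genotype = geno,
          replicate = seq_len(n_replicates), value = v,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "corrupted") <- if (length(corrupted)) {
      do.call(rbind, corrupted)
    } else {
      data.frame(gene = character(0), genotype = character(0),
                 replicate = integer(0))
    }
    out
  })
}

#' Build a signed fold-change table from replicated expression values
#'
#' Per gene and genotype: apply [replicate_filter()] when exactly three
#' replicates are present (otherwise use all), take means and SDs over the
#' kept replicates, then compute the signed MUT vs WT fold change rounded
#' half away from zero to `round_digits`. Records are sorted within
#' category by descending signed fold, ties broken alphabetically.
#'
#' @param expr Long data frame `gene,genotype,replicate,value` (and
#'   optionally `category`), as written by [simulate_expression()].
#' @param reference,alternative Genotype labels for the fold (default WT,
#'   MUT).
#' @param f_max Threshold for [replicate_filter()].
#' @param round_digits Display rounding (default 1 decimal).
#' @return A `fold_table` data frame: `gene,category,wt_mean,wt_sd,
#'   het_mean,het_sd,mut_mean,mut_sd,fold,fold_display,flagged` (flagged is
#'   a semicolon list of `genotype:replicate` entries).
#' @export
build_fold_table <- function(expr, reference = "WT", alternative = "MUT",
                             f_max = 0.5, round_digits = 1L) {
  need <- c("gene", "genotype", "replicate", "value")
  if (!all(need %in% names(expr))) {
    stop("expression table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"category" %in% names(expr)) expr$category <- "unassigned"
  recs <- lapply(split(expr, expr$gene), function(d) {
    geno_stats <- list(); flags <- character(0)
    for (geno in unique(d$genotype)) {
      v <- d$value[d$genotype == geno]
      if (length(v) == 3L) {
        rf <- replicate_filter(v, f_max = f_max)
        if (!is.na(rf$flagged)) {
          flags <- c(flags, paste0(geno, ":", rf$flagged))
        }
        geno_stats[[geno]] <- c(mean = rf$mean, sd = rf$sd)
      } else {
        geno_stats[[geno]] <- c(mean = mean(v),
                                sd = if (length(v) >= 2) stats::sd(v)
                                     else NA_real_)
      }
    }
    if (!all(c(reference, alternative) %in% names(geno_stats))) {
      stop("gene ", d$gene[1], " lacks ", reference, " or ", alternative,
           " replicates", call. = FALSE)
    }
    gm <- function(g, f) if (g %in% names(geno_stats)) geno_stats[[g]][[f]]
                         else NA_real_
    fold <- signed_fold(gm(reference, "mean"), gm(alternative, "mean"))
    data.frame(
      gene = d$gene[1], category = d$category[1],
      wt_mean = gm("WT", "mean"), wt_sd = gm("WT", "sd"),
      het_mean = gm("HET", "mean"), het_sd = gm("HET", "sd"),
      mut_mean = gm("MUT", "mean"), mut_sd = gm("MUT", "sd"),
      fold = fold,
      fold_display = round_half_away(fold, round_digits),
      flagged = paste(flags, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, recs)
  tab <- tab[order(tab$category, -tab$fold, tab$gene), ]
  rownames(tab) <- NULL
  class(tab) <- c("fold_table", "data.frame")
  tab
}

#' Top candidates per category by fold-change magnitude
#'
#' @param table A `fold_table`.
#' @param top_n Number of genes to keep per category (>= 1).
#' @return Subset of `table`, per category the `top_n` genes by descending
#'   |fold|, ties broken alphabetically by gene symbol.
#' @export
rank_candidates <- function(table, top_n) {
  stop_field(is.numeric(top_n) && top_n >= 1, "top_n", "must be >= 1")
  out <- lapply(split(table, table$category), function(d) {
    d <- d[order(-abs(d$fold), d$gene), ]
    utils::head(d, top_n)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Published candidate-gene group means
#'
#' Loads the packaged table of cytoskeletal/adhesion candidate genes with
#' their published per-genotype expression means and SDs (WT, HET, MUT of
#' the Pitx2-mutant migratory muscle progenitor series) and the printed
#' 1-decimal signed fold change.
#'
#' @return Data frame `gene,category,wt_mean,wt_sd,het_mean,het_sd,
#'   mut_mean,mut_sd,printed_fold,footnote`.
#' @export
candidate_gene_means <- function() {
  path <- system.file("extdata", "candidate_gene_means.tsv",
                      package = "motanlage", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
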