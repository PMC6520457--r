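#' Configuration for a simulated paired dropout screen
#'
#' Defines the study conditions of a simulated genome-wide negative-selection
#' screen in two cell lines sampled over a time course. Defaults mirror a
#' genome-wide rat knockout library: 19,840 genes with 3 sgRNAs each plus 10
#' non-targeting controls (59,530 guides), samples at days 1, 4, 11 and 21
#' with day 1 as reference, and sequencing at 300x mean coverage per guide.
#'
#' `class_fractions` are the mixture weights over the nine group archetypes
#' of the sign-by-significance classification (see [classify_gene()]):
#' archetype g determines the fitness signs in cell lines A and B. The
#' default composition is that of a typical dropout screen in a
#' primary/transformed pair: a large doubly-neutral bulk, a substantial
#' transformed-only essential class (group 8), and small minority classes
#' covering the remaining archetypes.
#'
#' @param n_genes Number of targeting genes (default 19840).
#' @param sgrnas_per_gene sgRNAs per gene (default 3).
#' @param n_controls Non-targeting control sgRNAs (default 10).
#' @param days Sampling days; the smallest is the reference (default
#'   `c(1, 4, 11, 21)`).
#' @param coverage Mean sequencing reads per sgRNA per sample (default 300).
#' @param cell_lines Two cell-line names, role A = primary first, role B =
#'   transformed second (default `c("A", "B")`).
#' @param class_fractions Numeric vector of 9 mixture weights over the group
#'   archetypes, summing to 1.
#' @param effect_size Per-day log2 fitness magnitude of a depleted gene
#'   (default 0.25: 20 days from day 1 to day 21 gives 5 log2 units,
#'   i.e. 32-fold depletion at full guide efficiency).
#' @param enrichment_scale Multiplier applied to `effect_size` for enriched
#'   (growth-suppressive) archetypes (default 0.2). Knockout of a growth
#'   suppressor confers a modest proliferative advantage, whereas knockout
#'   of an essential gene can abolish growth entirely, so enrichment is
#'   simulated weaker than depletion.
#' @param efficiency_dist Parameters `shape1`, `shape2` of the Beta
#'   distribution of per-sgRNA knockout efficiencies (default
#'   `list(shape1 = 17, shape2 = 3)`, mean 0.85).
#' @param abundance_sigma SD of the initial log2 guide abundances
#'   (log-normal cloning skew, default 0.5 log2 units).
#' @param dispersion Overdispersion of the sequencing sampling: 0 (default)
#'   draws pure multinomial counts, > 0 draws Dirichlet-multinomial counts
#'   with concentration `probability / dispersion`.
#' @param bottleneck Optional integer: number of cells surviving an initial
#'   transduction/selection bottleneck applied per cell line before day 1
#'   (default `NULL`, no bottleneck).
#' @param n_replicates Replicates per (cell line, day) (default 1).
#' @param control_label Reserved `gene_id` of control records.
#' @param seed RNG seed; every `simulate_*` output is a pure function of
#'   (config, seed).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 19840L,
                       sgrnas_per_gene = 3L,
                       n_controls = 10L,
                       days = c(1, 4, 11, 21),
                       coverage = 300,
                       cell_lines = c("A", "B"),
                       class_fractions = c(0.002, 0.02, 0.003,
                                           0.02, 0.75, 0.02,
                                           0.02, 0.155, 0.01),
                       effect_size = 0.25,
                       enrichment_scale = 0.2,
                       efficiency_dist = list(shape1 = 17, shape2 = 3),
                       abundance_sigma = 0.5,
                       dispersion = 0,
                       bottleneck = NULL,
                       n_replicates = 1L,
                       control_label = "non-targeting",
                       seed = 1L) {
  stopifnot(n_genes >= 1, sgrnas_per_gene >= 1, n_controls >= 0,
            length(days) >= 2, all(days >= 0), coverage > 0,
            length(cell_lines) == 2, effect_size >= 0,
            enrichment_scale >= 0, abundance_sigma >= 0, dispersion >= 0,
            n_replicates >= 1)
  if (length(class_fractions) != 9L || any(class_fractions < 0)) {
    stop("class_fractions must be 9 non-negative mixture weights")
  }
  if (abs(sum(class_fractions) - 1) > 1e-8) {
    stop("class_fractions must sum to 1 (got ", sum(class_fractions), ")")
  }
  if (anyDuplicated(cell_lines)) stop("cell_lines must be distinct")
  structure(list(n_genes = as.integer(n_genes),
                 sgrnas_per_gene = as.integer(sgrnas_per_gene),
                 n_controls = as.integer(n_controls),
                 days = sort(as.numeric(days)),
                 coverage = coverage,
                 cell_lines = as.character(cell_lines),
                 class_fractions = as.numeric(class_fractions),
                 effect_size = effect_size,
                 enrichment_scale = enrichment_scale,
                 efficiency_dist = efficiency_dist,
                 abundance_sigma = abundance_sigma,
                 dispersion = dispersion,
                 bottleneck = bottleneck,
                 n_replicates = as.integer(n_replicates),
                 control_label = control_label,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# archetype g -> fitness signs (sign_a, sign_b); rows of the 3x3 group grid:
# B sig up = groups 1:3, B ns = 4:6, B sig down = 7:9;
# columns A sig down = {1,4,7}, A ns = {2,5,8}, A sig up = {3,6,9}.
group_signs <- function(group) {
  sign_a <- c(-1L, 0L, 1L)[(group - 1L) %% 3L + 1L]
  sign_b <- c(1L, 0L, -1L)[(group - 1L) %/% 3L + 1L]
  cbind(sign_a = sign_a, sign_b = sign_b)
}

# inverse: fitness sign pattern -> implied true group
signs_to_group <- function(sign_a, sign_b) {
  (2L - sign_b) * 3L + (sign_a + 2L) - 3L
}

#' Simulate an sgRNA library
#'
#' Generates `n_genes * sgrnas_per_gene` targeting records plus
#' `n_controls` non-targeting controls with unique random 20-nt spacers.
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An `sgrna_library` (see [read_library()]).
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_targeting <- config$n_genes * config$sgrnas_per_gene
  n <- n_targeting + config$n_controls
  spacers <- random_spacers(n, width = 20L)
  gene_ids <- sprintf("g%05d", seq_len(config$n_genes))
  lib <- data.frame(
    sgrna_id = c(paste0(rep(gene_ids, each = config$sgrnas_per_gene), "_sg",
                        rep(seq_len(config$sgrnas_per_gene), config$n_genes)),
                 sprintf("ctrl_%03d", seq_len(config$n_controls))),
    gene_id = c(rep(gene_ids, each = config$sgrnas_per_gene),
                rep(config$control_label, config$n_controls)),
    spacer = spacers,
    stringsAsFactors = FALSE)
  sgrna_library(lib, control_label = config$control_label)
}

random_spacers <- function(n, width = 20L, max_tries = 25L) {
  draw <- function(k) {
    m <- matrix(sample(c("A", "C", "G", "T"), k * width, replace = TRUE),
                nrow = k)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  spacers <- draw(n)
  tries <- 0L
  while (anyDuplicated(spacers) > 0L) {
    tries <- tries + 1L
    if (tries > max_tries) stop("could not generate ", n, " unique spacers")
    dup <- which(duplicated(spacers))
    spacers[dup] <- draw(length(dup))
  }
  spacers
}

#' Plant per-gene fitness effects
#'
#' Assigns every targeting gene to one of the nine group archetypes by the
#' configured mixture weights; the archetype fixes the sign of the gene's
#' fitness in each cell line, and the magnitude is `effect_size` log2
#' units/day for depletion or `effect_size * enrichment_scale` for
#' enrichment. Per-sgRNA knockout efficiencies are Beta-distributed;
#' controls are neutral. Deterministic given `config$seed`.
#'
#' @param library An `sgrna_library` from [simulate_library()].
#' @param config A [sim_config()].
#' @return A list of class `fitness_truth` with elements `genes` (data
#'   frame: `gene_id`, `true_group`, `f_a`, `f_b` in log2 units/day) and
#'   `sgrnas` (data frame: `sgrna_id`, `gene_id`, `efficiency`, controls
#'   at efficiency 1 and fitness 0).
#' @export
assign_fitness <- function(library, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  gene_ids <- unique(library$gene_id[!library$is_control])
  n <- length(gene_ids)
  grp <- sample(1:9, n, replace = TRUE, prob = config$class_fractions)
  sg <- group_signs(grp)
  magnitude <- function(s) {
    ifelse(s < 0, -config$effect_size,
           ifelse(s > 0, config$effect_size * config$enrichment_scale, 0))
  }
  genes <- data.frame(gene_id = gene_ids, true_group = grp,
                      f_a = magnitude(sg[, "sign_a"]),
                      f_b = magnitude(sg[, "sign_b"]),
                      stringsAsFactors = FALSE, row.names = NULL)
  eff <- rbeta(nrow(library), config$efficiency_dist$shape1,
               config$efficiency_dist$shape2)
  eff[library$is_control] <- 1
  sgrnas <- data.frame(sgrna_id = library$sgrna_id,
                       gene_id = library$gene_id,
                       efficiency = eff,
                       stringsAsFactors = FALSE, row.names = NULL)
  structure(list(genes = genes, sgrnas = sgrnas,
                 cell_lines = config$cell_lines),
            class = "fitness_truth")
}

#' Simulate screen counts from planted fitness effects
#'
#' Models the relative abundance of sgRNA s in cell line c at day t as
#' `pi_s * 2^(e_s * f_{g(s),c} * (t - t_ref))`, with `pi_s` a log-normal
#' initial abundance shared by both cell lines (cloning skew), `e_s` the
#' guide efficiency and `f` the planted per-day log2 fitness; fitness acts
#' over the days elapsed since the reference day. Observed counts per
#' sample are multinomial with total `round(coverage * library size)`
#' (Dirichlet-multinomial when `dispersion > 0`). An optional transduction
#' bottleneck subsamples the initial pool per cell line before day 1.
#' Deterministic given `config$seed`.
#'
#' @param library An `sgrna_library`.
#' @param truth A `fitness_truth` from [assign_fitness()].
#' @param config A [sim_config()].
#' @return A `screen_counts` object (see [screen_counts()]).
#' @export
simulate_counts <- function(library, truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "fitness_truth"))
  set.seed(config$seed + 2L)
  n <- nrow(library)
  total <- round(config$coverage * n)
  pi0 <- 2^rnorm(n, 0, config$abundance_sigma)
  eff <- truth$sgrnas$efficiency[match(library$sgrna_id,
                                       truth$sgrnas$sgrna_id)]
  gidx <- match(library$gene_id, truth$genes$gene_id)  # NA for controls
  ref_day <- min(config$days)
  samples <- expand.grid(replicate = seq_len(config$n_replicates),
                         day = config$days,
                         cell_line = config$cell_lines,
                         stringsAsFactors = FALSE)
  samples <- samples[, c("cell_line", "day", "replicate")]
  samples$sample_id <- paste0(samples$cell_line, "_d", samples$day,
                              "_r", samples$replicate)
  counts <- matrix(0L, nrow = n, ncol = nrow(samples),
                   dimnames = list(library$sgrna_id, samples$sample_id))
  for (cl in config$cell_lines) {
    f <- if (cl == config$cell_lines[1L]) truth$genes$f_a else truth$genes$f_b
    f_sg <- ifelse(is.na(gidx), 0, f[gidx]) * eff
    pool <- pi0
    if (!is.null(config$bottleneck)) {
      taken <- rmultinom(1L, size = as.integer(config$bottleneck),
                         prob = pool / sum(pool))[, 1L]
      pool <- as.numeric(taken)
    }
    for (j in which(samples$cell_line == cl)) {
      w <- pool * 2^(f_sg * (samples$day[j] - ref_day))
      prob <- w / sum(w)
      if (config$dispersion > 0) {
        g <- rgamma(n, shape = prob / config$dispersion, rate = 1)
        if (sum(g) == 0) g <- prob
        prob <- g / sum(g)
      }
      counts[, j] <- rmultinom(1L, size = total, prob = prob)[, 1L]
    }
  }
  screen_counts(counts, samples[, c("sample_id", "cell_line", "day",
                                    "replicate")])
}

#' Simulate a complete paired screen
#'
#' Convenience wrapper running [simulate_library()], [assign_fitness()] and
#' [simulate_counts()].
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_screen` with elements `library`, `truth`,
#'   `counts` and `config`.
#' @export
simulate_screen <- function(config) {
  library <- simulate_library(config)
  truth <- assign_fitness(library, config)
  counts <- simulate_counts(library, truth, config)
  structure(list(library = library, truth = truth, counts = counts,
                 config = config),
            class = "sim_screen")
}

# fixed vector context flanking the spacer in simulated reads (U6 promoter
# tail / scaffold head of the expression cassette)
.read_flank5 <- "TATCTTGTGGAAAGGACGAAACACCG"
.read_flank3 <- "GTTTTAGAGCTAGAAATAGCAAG"

#' Emit simulated FASTQ reads for one sample
#'
#' Writes, for every sgRNA, `count`-many reads containing the spacer
#' embedded in fixed vector context, so that [count_spacers()] on the
#' output reproduces the sample's counts exactly. Deterministic given
#' `config$seed` (reads are emitted in library order).
#'
#' @param screen A `sim_screen` from [simulate_screen()], or a list with
#'   elements `library` and `counts`.
#' @param sample_id Sample column to emit.
#' @param path Output FASTQ path; with `path = NULL` the read sequences are
#'   returned as a character vector instead.
#' @return `path` invisibly, or the reads when `path = NULL`.
#' @export
simulate_reads <- function(screen, sample_id, path = NULL) {
  library <- screen$library
  counts <- screen$counts
  stopifnot(inherits(counts, "screen_counts"))
  if (!sample_id %in% colnames(counts$counts)) {
    stop("sample '", sample_id, "' not present in counts")
  }
  k <- counts$counts[, sample_id]
  reads <- rep(paste0(.read_flank5, library$spacer, .read_flank3), k)
  ids <- rep(library$sgrna_id, k)
  if (is.null(path)) return(reads)
  if (length(reads) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  qual <- strrep("I", nchar(reads))
  fq <- as.vector(rbind(paste0("@", ids, ":", sequence(k)),
                        reads, "+", qual))
  writeLines(fq, path)
  invisible(path)
}

#' Score recovery of the planted classification
#'
#' Compares called groups against the simulator's planted truth over the
#' same gene universe.
#'
#' @param rows A `gene_class_table` from [classify_screen()].
#' @param truth A `fitness_truth` from [assign_fitness()].
#' @return A list of class `recovery_eval` with elements `confusion` (9 x 9
#'   matrix, rows = true group, columns = called group), `precision` and
#'   `recall` (per-group, `NaN` where undefined) and `accuracy`.
#' @export
evaluate_recovery <- function(rows, truth) {
  stopifnot(inherits(truth, "fitness_truth"), "group" %in% names(rows))
  if (!setequal(rows$gene_id, truth$genes$gene_id)) {
    stop("classified genes and truth genes are not the same universe")
  }
  true_grp <- truth$genes$true_group[match(rows$gene_id,
                                           truth$genes$gene_id)]
  confusion <- table(factor(true_grp, levels = 1:9),
                     factor(rows$group, levels = 1:9))
  confusion <- unclass(confusion)
  dimnames(confusion) <- list(true = as.character(1:9),
                              called = as.character(1:9))
  d <- diag(confusion)
  structure(list(confusion = confusion,
                 precision = d / colSums(confusion),
                 recall = d / rowSums(confusion),
                 accuracy = sum(d) / sum(confusion)),
            class = "recovery_eval")
}

#' @export
print.recovery_eval <- function(x, ...) {
  cat("classification recovery: accuracy ",
      format(x$accuracy, digits = 3), "\n", sep = "")
  cat("group 8 precision ", format(x$precision[["8"]], digits = 3),
      ", recall ", format(x$recall[["8"]], digits = 3), "\n", sep = "")
  invisible(x)
}
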