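#' Read a replicate metabolomics table
#'
#' Accepts either the long format (columns \code{metabolite},
#' \code{timepoint}, \code{replicate}, \code{value}, optional
#' \code{platform}) or a wide format in which the first column is the
#' metabolite and the remaining column names encode
#' \code{<timepoint>_<replicate>} (e.g. \code{0h_1}, \code{3h_2}).
#'
#' @param path CSV or TSV path (delimiter inferred from the extension,
#'   \code{.tsv}/\code{.txt} means tab).
#' @param format \code{"long"} (default) or \code{"wide"}.
#' @return data.frame with columns \code{base_name}, \code{timepoint},
#'   \code{replicate}, \code{peak_area}.
#' @export
read_metabolomics <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (format == "long") {
    need <- c("metabolite", "timepoint", "replicate", "value")
    if (!all(need %in% names(df))) {
      stop("long-format table must have columns: ", paste(need, collapse = ", "))
    }
    out <- data.frame(base_name = as.character(df$metabolite),
                      timepoint = as.character(df$timepoint),
                      replicate = as.integer(df$replicate),
                      peak_area = as.numeric(df$value),
                      stringsAsFactors = FALSE)
  } else {
    cols <- names(df)[-1]
    parts <- regmatches(cols, regexec("^(.*)_([0-9]+)$", cols))
    bad <- vapply(parts, length, 0L) != 3
    if (any(bad)) {
      stop("wide-format column names must look like <timepoint>_<replicate>: ",
           paste(cols[bad], collapse = ", "))
    }
    out <- do.call(rbind, lapply(seq_along(cols), function(j) {
      data.frame(base_name = as.character(df[[1]]),
                 timepoint = parts[[j]][2],
                 replicate = as.integer(parts[[j]][3]),
                 peak_area = as.numeric(df[[j + 1]]),
                 stringsAsFactors = FALSE)
    }))
  }
  if (any(out$peak_area < 0, na.rm = TRUE)) stop("negative peak areas in ", path)
  out
}

#' Exact or approximate two-sided Mann-Whitney U p-value
#'
#' Two-sided rank-sum test between two samples.  The exact path uses the
#' closed-form null distribution (\code{stats::pwilcox}) when the pooled
#' data contain no ties, and full enumeration over all
#' \eqn{\binom{n+m}{n}} group assignments of the midrank-tied pooled sample
#' otherwise (feasible at the small replicate counts of targeted
#' metabolomics).  The normal path applies the tie-corrected variance and a
#' 0.5 continuity correction, matching \code{stats::wilcox.test(correct =
#' TRUE)}.  Two-sided p is \code{min(1, 2 * min(P(U <= u), P(U >= u)))}.
#'
#' @param x,y numeric samples.
#' @param method \code{"exact"} or \code{"normal"}.
#' @return list with \code{p_value} and the U statistic \code{u} for x.
#' @export
mwu_test <- function(x, y, method = c("exact", "normal")) {
  method <- match.arg(method)
  n <- length(x); m <- length(y)
  stopifnot(n >= 1, m >= 1)
  pooled <- c(x, y)
  r <- rank(pooled)                       # midranks
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (method == "exact") {
    if (n + m > 20) {
      stop("exact method is limited to n + m <= 20; use method = 'normal'")
    }
    if (!ties) {
      p_le <- stats::pwilcox(u, n, m)
      p_ge <- stats::pwilcox(u - 1, n, m, lower.tail = FALSE)
    } else {
      # enumerate all assignments of n of the pooled midranks to group x
      idx <- utils::combn(n + m, n)
      sums <- colSums(matrix(r[idx], nrow = n))
      us <- sums - n * (n + 1) / 2
      eps <- 1e-9
      p_le <- mean(us <= u + eps)
      p_ge <- mean(us >= u - eps)
    }
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * m / 2
    nt <- table(pooled)
    sigma2 <- n * m / 12 *
      ((n + m + 1) - sum(nt^3 - nt) / ((n + m) * (n + m - 1)))
    if (sigma2 <= 0) return(list(p_value = 1, u = u))
    cc <- sign(u - mu) * 0.5              # continuity correction toward the mean
    z <- (u - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(p_value = p, u = u)
}

#' Call statistically significant metabolites (SSMs)
#'
#' For each measured metabolite, compares replicate peak areas between two
#' timepoints with a two-sided Mann-Whitney U test and flags the metabolite
#' as an SSM when \code{p < alpha}.  Direction is the sign of the shift in
#' medians from \code{t0} to \code{t1} (\code{accumulated} /
#' \code{depleted}); a significant p with exactly tied medians has no
#' direction, so the SSM flag is withdrawn (with a message).  Metabolites
#' observed at only one of the two timepoints get \code{p = 1},
#' \code{direction = "none"}.
#'
#' No multiple-testing correction is applied by default (raw \code{p <
#' alpha}); set \code{p_adjust = "BH"} for Benjamini-Hochberg.
#'
#' @param data data.frame as returned by [read_metabolomics()].
#' @param t0,t1 timepoint labels to compare.
#' @param alpha significance threshold in (0, 1).
#' @param method \code{"auto"} (exact when both groups have at most 8
#'   replicates, else normal approximation), \code{"exact"}, or
#'   \code{"normal"}.
#' @param p_adjust \code{"none"} (default) or any method accepted by
#'   [stats::p.adjust()]; adjustment is applied before thresholding.
#' @return an \code{ssm_table}: data.frame with columns \code{base_name},
#'   \code{n0}, \code{n1}, \code{p_value}, \code{direction}
#'   (\code{accumulated}/\code{depleted}/\code{none}), \code{is_ssm}.
#' @export
call_ssms <- function(data, t0, t1, alpha = 0.05,
                      method = c("auto", "exact", "normal"),
                      p_adjust = "none") {
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha < 1)
  for (tp in c(t0, t1)) {
    if (!tp %in% data$timepoint) stop("timepoint label not in data: ", tp)
  }
  mets <- unique(data$base_name)
  rows <- lapply(mets, function(met) {
    x <- data$peak_area[data$base_name == met & data$timepoint == t0]
    y <- data$peak_area[data$base_name == met & data$timepoint == t1]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) == 0 || length(y) == 0) {
      warning("metabolite '", met, "' missing replicates at one timepoint; p set to 1")
      return(data.frame(base_name = met, n0 = length(x), n1 = length(y),
                        p_value = 1, direction = "none", stringsAsFactors = FALSE))
    }
    use <- if (method == "auto") {
      if (max(length(x), length(y)) <= 8) "exact" else "normal"
    } else method
    p <- mwu_test(x, y, method = use)$p_value
    shift <- stats::median(y) - stats::median(x)
    dir <- if (shift > 0) "accumulated" else if (shift < 0) "depleted" else "none"
    data.frame(base_name = met, n0 = length(x), n1 = length(y),
               p_value = p, direction = dir, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!identical(p_adjust, "none")) {
    out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  }
  out$is_ssm <- out$p_value < alpha & out$direction != "none"
  undirected <- out$p_value < alpha & out$direction == "none"
  if (any(undirected)) {
    message(sum(undirected), " metabolite(s) significant but with tied medians; ",
            "not called SSM: ", paste(out$base_name[undirected], collapse = ", "))
  }
  attr(out, "alpha") <- alpha
  class(out) <- c("ssm_table", "data.frame")
  out
}

#' Expand SSM calls to compartmentalized model nodes
#'
#' Peak areas come from whole-tissue extracts, so a significant measurement
#' cannot be attributed to one compartment: every compartmental version of
#' an SSM base name in the model is treated as an SSM node.
#'
#' @param ssm_table result of [call_ssms()].
#' @param compartment_map result of [load_compartment_map()].
#' @param model a \code{metabolic_model}.
#' @return the table with attribute \code{ssm_nodes} (character vector of
#'   model node ids) and attribute \code{unmatched_ssms} (SSM base names
#'   with no mapping into the model).  SSM flags are never altered.
#' @export
expand_to_model <- function(ssm_table, compartment_map, model) {
  ssm_names <- ssm_table$base_name[ssm_table$is_ssm]
  mapped <- intersect(ssm_names, names(compartment_map))
  nodes <- as.character(unique(unlist(compartment_map[mapped], use.names = FALSE)))
  nodes <- intersect(nodes, model$metabolites$node_id)
  unmatched <- setdiff(ssm_names, mapped)
  if (length(unmatched)) {
    warning(length(unmatched), " SSM base name(s) with no model mapping: ",
            paste(utils::head(unmatched, 5), collapse = ", "))
  }
  attr(ssm_table, "ssm_nodes") <- nodes
  attr(ssm_table, "unmatched_ssms") <- unmatched
  ssm_table
}

#' @rdname expand_to_model
#' @export
ssm_nodes <- function(ssm_table) {
  nodes <- attr(ssm_table, "ssm_nodes")
  if (is.null(nodes)) stop("ssm_table has not been expanded; run expand_to_model()")
  nodes
}

#' Write an SSM table (and expanded node list) to TSV
#'
#' @param ssm_table result of [call_ssms()] (optionally expanded).
#' @param path output TSV for the per-metabolite table.
#' @param nodes_path optional output TSV for the expanded node list (one
#'   node id per row); requires a prior [expand_to_model()].
#' @return \code{path}, invisibly.
#' @export
write_ssm_table <- function(ssm_table, path, nodes_path = NULL) {
  utils::write.table(as.data.frame(ssm_table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(nodes_path)) {
    utils::write.table(data.frame(node_id = ssm_nodes(ssm_table)), nodes_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
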