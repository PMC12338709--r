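#' Read a long-format study table from CSV
#'
#' One header line, UTF-8, '.' decimal. Validates that the schema columns
#' needed downstream are present.
#'
#' @param path CSV file path.
#' @param require character vector of columns that must be present.
#' @return data.frame.
#' @export
readStudyTable <- function(path,
                           require = c("participant", "session", "method")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(require, names(d))
  if (length(miss)) {
    stop("study CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' Write a study table to CSV
#'
#' @param study data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeStudyTable <- function(study, path) {
  utils::write.csv(study, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full statistical battery on a quantified study table
#'
#' Fits the Method x Session model to the concentration (and, when
#' present, to each tissue-fraction column), computes Tukey pairwise
#' contrasts, within- and between-method percent differences, and — when
#' an `age` column is present — Pearson associations of age with
#' normalized GM fraction and with concentration per method, plus
#' Steiger's Z comparisons between methods.
#'
#' @param study quantified study table (needs `conc_mM`; see
#'   [quantifyStudy()]).
#' @param metabolite metabolite to analyze (default: the single one
#'   present).
#' @return list of class `mrsqStatReport` with elements `anova`, `means`,
#'   `contrasts`, `percent_differences`, `correlations`, `steiger`,
#'   `normality`.
#' @export
compareStudy <- function(study, metabolite = NULL) {
  if (!"conc_mM" %in% names(study)) {
    stop("study table has no conc_mM column; run quantifyStudy() first",
         call. = FALSE)
  }
  if (is.null(metabolite)) {
    mets <- unique(study$metabolite)
    if (length(mets) != 1L) {
      stop("several metabolites present; pass `metabolite`", call. = FALSE)
    }
    metabolite <- mets
  }
  d <- study[study$metabolite == metabolite, , drop = FALSE]
  fit <- methodSessionModel(d, "conc_mM")
  contrasts <- tukeyPairwise(fit)
  methods <- sort(unique(d$method))

  within <- do.call(rbind, lapply(methods, function(m) {
    sessionPercentChange(d, m, metabolite = metabolite)
  }))
  pairs <- utils::combn(methods, 2)
  between <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    betweenMethodPercentDifference(d, pairs[1, j], pairs[2, j],
                                   metabolite = metabolite)
  }))
  within$group_pct <- NA_real_
  pct <- rbind(within, between)

  normality <- shapiroNormalityScreen(d, "conc_mM",
                                      groups = c("metabolite", "method",
                                                 "session"))

  correlations <- NULL
  steiger <- NULL
  if ("age" %in% names(d) &&
      all(c("f_gm", "f_wm") %in% names(d))) {
    perMethod <- lapply(methods, function(m) {
      dm <- d[d$method == m, , drop = FALSE]
      # session-averaged per participant
      ids <- sort(unique(dm$participant))
      g <- tapply(normalizedGM(dm), dm$participant, mean)[ids]
      cc <- tapply(dm$conc_mM, dm$participant, mean)[ids]
      a <- tapply(dm$age, dm$participant, mean)[ids]
      list(method = m, age = a, normGM = g, conc = cc)
    })
    correlations <- do.call(rbind, lapply(perMethod, function(x) {
      rbind(
        cbind(method = x$method, variable = "normalized_gm",
              pearsonAssociation(x$age, x$normGM)),
        cbind(method = x$method, variable = "conc_mM",
              pearsonAssociation(x$age, x$conc)))
    }))
    steigerFor <- function(var) {
      do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
        a <- perMethod[[match(pairs[1, j], methods)]]
        b <- perMethod[[match(pairs[2, j], methods)]]
        ya <- a[[var]]; yb <- b[[var]]
        z <- steigerDependentZ(stats::cor(a$age, ya), stats::cor(b$age, yb),
                               stats::cor(ya, yb), length(ya))
        data.frame(variable = if (var == "normGM") "normalized_gm" else "conc_mM",
                   pair = paste(pairs[1, j], pairs[2, j], sep = " - "),
                   z = z$z, p = z$p, stringsAsFactors = FALSE)
      }))
    }
    steiger <- rbind(steigerFor("normGM"), steigerFor("conc"))
  }

  structure(list(metabolite = metabolite,
                 anova = anovaTable(fit),
                 means = fit@means,
                 contrasts = contrasts,
                 percent_differences = pct,
                 normality = normality,
                 correlations = correlations,
                 steiger = steiger),
            class = "mrsqStatReport")
}

#' Write a statistical report to JSON
#'
#' @param report an `mrsqStatReport` (from [compareStudy()]).
#' @param path output .json path.
#' @param provenance optional named list embedded under `provenance`.
#' @return `path`, invisibly.
#' @export
writeStatReportJSON <- function(report, path, provenance = NULL) {
  obj <- unclass(report)
  obj$provenance <- provenance
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a statistical report back from JSON
#'
#' @param path .json path written by [writeStatReportJSON()].
#' @return an `mrsqStatReport` list.
#' @export
readStatReportJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "mrsqStatReport")
}

fmt2 <- function(x) formatC(x, format = "f", digits = 2)

fmtP <- function(p) ifelse(p < 1e-4, "< 0.0001", fmt2(p))

mdTable <- function(df) {
  cells <- vapply(df, function(col) {
    if (is.numeric(col)) fmt2(col) else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(toupper(names(df)), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Render a markdown report of the statistical outputs
#'
#' Deterministic layout: methods alphabetical, pairs canonical, numbers to
#' two decimals; a provenance block (config hash, seed, package version)
#' makes reruns auditable. The contrast table mirrors the
#' estimate/SE/df/t-ratio/p layout of a Tukey pairwise table.
#'
#' @param report an `mrsqStatReport` (from [compareStudy()] or
#'   [readStatReportJSON()]).
#' @param path output .md path.
#' @param provenance optional named list (e.g. config_hash, seed).
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, provenance = NULL) {
  contrasts <- as.data.frame(report$contrasts)
  if (is.null(contrasts) || !nrow(contrasts)) {
    stop("empty contrast table: nothing to report", call. = FALSE)
  }
  contrasts <- contrasts[order(contrasts$pair), , drop = FALSE]
  lines <- c(
    sprintf("# Segmentation-propagation report: %s", report$metabolite),
    "",
    "## Provenance",
    "")
  prov <- c(list(package = paste0("mrsq ",
                                  as.character(utils::packageVersion("mrsq")))),
            provenance)
  lines <- c(lines, vapply(names(prov), function(k) {
    sprintf("- %s: %s", k, as.character(prov[[k]]))
  }, ""), "")

  anova <- as.data.frame(report$anova)
  anova$p <- fmtP(anova$p)
  lines <- c(lines, "## Fixed effects (Method x Session, participant intercepts)",
             "", mdTable(anova), "")

  means <- as.data.frame(report$means)
  means <- means[order(means$factor, means$level), , drop = FALSE]
  lines <- c(lines, "## Estimated marginal means (95% CI)", "",
             mdTable(means), "")

  ctab <- data.frame(method = contrasts$pair,
                     estimate = contrasts$estimate,
                     se = contrasts$se,
                     df = contrasts$df,
                     t_ratio = contrasts$t_ratio,
                     p_value = fmtP(contrasts$p_adjusted))
  lines <- c(lines, "## Tukey-adjusted pairwise comparisons", "",
             mdTable(ctab), "")

  if (!is.null(report$percent_differences)) {
    pct <- as.data.frame(report$percent_differences)
    pct <- pct[order(pct$scope, pct$labels), , drop = FALSE]
    lines <- c(lines, "## Percent differences", "", mdTable(pct), "")
  }
  if (!is.null(report$correlations) && length(report$correlations)) {
    corr <- as.data.frame(report$correlations)
    corr <- corr[order(corr$variable, corr$method), , drop = FALSE]
    lines <- c(lines, "## Age associations (Pearson)", "", mdTable(corr), "")
  }
  if (!is.null(report$steiger) && length(report$steiger)) {
    st <- as.data.frame(report$steiger)
    st <- st[order(st$variable, st$pair), , drop = FALSE]
    lines <- c(lines, "## Steiger's Z (dependent correlations)", "",
               mdTable(st), "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Plot method marginal means with 95% confidence intervals
#'
#' A minimal companion figure to the pairwise table (requires ggplot2).
#'
#' @param fit a [MethodSessionFit-class] object.
#' @return a ggplot object.
#' @export
plotMethodMeans <- function(fit) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  mm <- marginalMeans(fit, "method")
  ggplot2::ggplot(mm, ggplot2::aes(x = level, y = mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = ci_low, ymax = ci_high),
                           width = 0.15) +
    ggplot2::labs(x = "Segmentation method",
                  y = fit@design$response) +
    ggplot2::theme_minimal()
}
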