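# Per-category summary tables, currency conversion, and scenario-comparison
# statistics (leakage accounting).

#' Round half away from zero
#'
#' Presentation rounding (5 rounds up), as used in the printed comparison
#' percentages; internal values are never rounded.
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Construct / validate a per-category summary table
#'
#' One row per land category plus a `total` row, with baseline commercial
#' stock (million m3), baseline area (million ha), harvested volume
#' (million m3), logged area (million ha) and net profit (million USD).
#'
#' @param df data.frame with columns `category`, `baseline_stock_Mm3`,
#'   `baseline_area_Mha`, `volume_Mm3`, `area_Mha`, `profit_musd`.
#' @return A `summary_table` data.frame.
#' @export
summary_table <- function(df) {
  cols <- c("category", "baseline_stock_Mm3", "baseline_area_Mha",
            "volume_Mm3", "area_Mha", "profit_musd")
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("schema error: summary table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"total" %in% df$category)
    stop("schema error: summary table needs a 'total' row", call. = FALSE)
  num <- df[df$category != "total", cols[-1]]
  if (nrow(num) && any(num < 0, na.rm = TRUE))
    stop("summary values must be >= 0", call. = FALSE)
  df <- df[cols]
  class(df) <- c("summary_table", "data.frame")
  df
}

#' Aggregate an annual ledger into a summary table
#'
#' Sums volume, newly logged area and net rent over years and centers per
#' land category, converts rent to USD at the given exchange rate, and adds
#' a grand-total row (categories are a partition of the landscape, so the
#' total is the column sum).
#'
#' @param ledger an [annual_ledger()].
#' @param exchange_rate BRL per USD (> 0); default is the 2009 average 1.995.
#' @return A [summary_table()].
#' @export
summarize_ledger <- function(ledger, exchange_rate = 1.995) {
  if (exchange_rate <= 0)
    stop("domain error: exchange rate must be > 0", call. = FALSE)
  base <- ledger$baseline
  rec <- ledger$records
  agg <- function(values, by) {
    out <- rep(0, nrow(base))
    if (length(values)) {
      s <- tapply(values, by, sum)
      out[match(names(s), base$category)] <- s
    }
    out
  }
  df <- data.frame(
    category = base$category,
    baseline_stock_Mm3 = base$stock_m3 / 1e6,
    baseline_area_Mha = base$area_ha / 1e6,
    volume_Mm3 = agg(rec$volume_m3, rec$category) / 1e6,
    area_Mha = agg(rec$new_area_ha, rec$category) / 1e6,
    profit_musd = agg(rec$rent_brl, rec$category) / exchange_rate / 1e6)
  total <- data.frame(category = "total", t(colSums(df[-1])))
  names(total) <- names(df)
  summary_table(rbind(df, total))
}

#' Compare two scenario summary tables
#'
#' Per category and metric: absolute difference and percent change
#' `(ILLEGAL - LEGAL) / LEGAL x 100`, plus the harvested fraction of the
#' baseline per category and scenario. Values are kept at full precision;
#' round at presentation with [round_half_up()].
#'
#' @param table_legal,table_illegal [summary_table()]s over the same
#'   categories and baselines.
#' @return A `scenario_comparison`: list with data.frames `changes`
#'   (category, metric, legal, illegal, diff, pct_change) and `fractions`
#'   (category, scenario, volume_pct_of_baseline, area_pct_of_baseline).
#' @export
compare_scenarios <- function(table_legal, table_illegal) {
  if (!identical(table_legal$category, table_illegal$category))
    stop("schema error: summary tables have mismatched categories", call. = FALSE)
  if (!isTRUE(all.equal(table_legal$baseline_stock_Mm3,
                        table_illegal$baseline_stock_Mm3)))
    stop("schema error: summary tables have mismatched baselines", call. = FALSE)

  metrics <- c("volume_Mm3", "area_Mha", "profit_musd")
  changes <- do.call(rbind, lapply(metrics, function(m) {
    l <- table_legal[[m]]; i <- table_illegal[[m]]
    data.frame(category = table_legal$category, metric = m,
               legal = l, illegal = i, diff = i - l,
               pct_change = ifelse(l > 0, (i - l) / l * 100, NA_real_))
  }))
  rownames(changes) <- NULL

  frac <- do.call(rbind, lapply(list(LEGAL = table_legal, ILLEGAL = table_illegal),
                                function(tb) {
    data.frame(category = tb$category,
               volume_pct_of_baseline =
                 ifelse(tb$baseline_stock_Mm3 > 0,
                        tb$volume_Mm3 / tb$baseline_stock_Mm3 * 100, NA_real_),
               area_pct_of_baseline =
                 ifelse(tb$baseline_area_Mha > 0,
                        tb$area_Mha / tb$baseline_area_Mha * 100, NA_real_))
  }))
  frac$scenario <- rep(c("LEGAL", "ILLEGAL"), each = nrow(table_legal))
  rownames(frac) <- NULL
  structure(list(changes = changes,
                 fractions = frac[c("category", "scenario",
                                    "volume_pct_of_baseline",
                                    "area_pct_of_baseline")]),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("<scenario_comparison> percent change, ILLEGAL vs LEGAL:\n")
  ch <- x$changes
  ch$pct_change <- round_half_up(ch$pct_change, 1)
  print(ch, row.names = FALSE)
  invisible(x)
}

#' Harvested fraction of the baseline for one category
#'
#' @param table a [summary_table()].
#' @param category a category name present in the table.
#' @param metric `"volume"` or `"area"`.
#' @return Percent of the baseline stock (volume) or total area (area)
#'   harvested, at full precision.
#' @export
fraction_of_baseline <- function(table, category, metric = c("volume", "area")) {
  metric <- match.arg(metric)
  i <- match(category, table$category)
  if (is.na(i)) stop("unknown category: ", category, call. = FALSE)
  base <- switch(metric, volume = table$baseline_stock_Mm3[i],
                 area = table$baseline_area_Mha[i])
  harv <- switch(metric, volume = table$volume_Mm3[i], area = table$area_Mha[i])
  if (base <= 0) stop("domain error: zero baseline for ", category, call. = FALSE)
  harv / base * 100
}

#' Published Amazon-scale scenario totals
#'
#' The per-category totals of the published Amazon application (2009
#' baseline, 30-year LEGAL and ILLEGAL runs on the real land-cover, zoning
#' and transport rasters), shipped as a reference dataset so the comparison
#' arithmetic can be reproduced without the proprietary inputs. The printed
#' `total` row covers the whole Brazilian Amazon and is larger than the sum
#' of the listed categories (protected and other land is not broken out).
#'
#' @return `list(LEGAL = summary_table, ILLEGAL = summary_table)`.
#' @export
amazon_reference_tables <- function() {
  path <- system.file("extdata", "amazon_published_totals.csv",
                      package = "timbersim", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  pick <- function(prefix) {
    out <- data.frame(category = df$category,
                      baseline_stock_Mm3 = df$baseline_stock_Mm3,
                      baseline_area_Mha = df$baseline_area_Mha,
                      volume_Mm3 = df[[paste0(prefix, "_volume_Mm3")]],
                      area_Mha = df[[paste0(prefix, "_area_Mha")]],
                      profit_musd = df[[paste0(prefix, "_profit_musd")]])
    summary_table(out)
  }
  list(LEGAL = pick("legal"), ILLEGAL = pick("illegal"))
}
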