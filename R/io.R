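# Delimited-text readers/writers for every pipeline artifact. All files are
# UTF-8 CSV with "." decimals; numbers are serialized with 17 significant
# digits so write -> read round-trips are bit-exact.

fmt_num <- function(x) {
  out <- vapply(x, function(v) sprintf("%.17g", v), character(1))
  out[x == round(x) & abs(x) < 1e15] <-
    sprintf("%.0f", x[x == round(x) & abs(x) < 1e15])
  out
}

write_csv_raw <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

read_csv_raw <- function(path, required, what) {
  if (!file.exists(path))
    stop("schema-error: missing file ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("schema-error: ", what, " (", basename(path),
         ") missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L)
    stop("schema-error: ", what, " (", basename(path), ") has no rows",
         call. = FALSE)
  df
}

#' Write a region to zones/brands/stores CSV files
#'
#' @param reg a [region()].
#' @param dir output directory (created if needed); writes `zones.csv`,
#'   `brands.csv`, `stores.csv`.
#' @return `dir`, invisibly.
#' @export
write_region <- function(reg, dir) {
  stopifnot(inherits(reg, "region"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_raw(reg$zones[, c("zone_id", "x_km", "y_km", "area_km2",
                              "population")],
                file.path(dir, "zones.csv"))
  write_csv_raw(reg$brands[, c("brand_id", "total_revenue")],
                file.path(dir, "brands.csv"))
  write_csv_raw(reg$stores[, intersect(c("store_id", "brand_id", "zone_id",
                                         "revenue", "weight"),
                                       names(reg$stores))],
                file.path(dir, "stores.csv"))
  invisible(dir)
}

#' Read a region from zones/brands/stores CSV files
#'
#' @param dir directory containing `zones.csv`, `brands.csv`, `stores.csv`.
#' @return A validated [region()].
#' @export
read_region <- function(dir) {
  zones <- read_csv_raw(file.path(dir, "zones.csv"),
                        c("zone_id", "x_km", "y_km", "area_km2",
                          "population"), "zones")
  brands <- read_csv_raw(file.path(dir, "brands.csv"),
                         c("brand_id", "total_revenue"), "brands")
  stores <- read_csv_raw(file.path(dir, "stores.csv"),
                         c("store_id", "brand_id", "zone_id"), "stores")
  region(zones, brands, stores)
}

#' Write a labelled square matrix to CSV
#'
#' First row and first column carry the zone (node) labels.
#'
#' @param m matrix with identical row and column names.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    stop("schema-error: matrix must carry matching row/column labels",
         call. = FALSE)
  df <- data.frame(id = rownames(m), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- m[, j]
  write_csv_raw(df, path)
  invisible(path)
}

#' Read a labelled square matrix from CSV
#'
#' @param path file written by [write_matrix()].
#' @return Matrix with matching row/column labels.
#' @export
read_matrix <- function(path) {
  df <- read_csv_raw(path, "id", "matrix")
  ids <- as.character(df$id)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) != ncol(m))
    stop("schema-error: matrix is not square", call. = FALSE)
  cn <- colnames(m)
  # read.csv mangles labels that are not syntactic names; compare mangled
  if (!identical(make.names(ids, unique = TRUE), make.names(cn, unique = TRUE)))
    stop("schema-error: row labels do not match column labels", call. = FALSE)
  dimnames(m) <- list(ids, ids)
  m
}

#' Write a supply network as an edge list plus node-partition header
#'
#' @param net a `supply_network`.
#' @param dir output directory; writes `edges.csv`
#'   (`src_id,dst_id,prob`) and `nodes.json` (transient/absorbing
#'   partition).
#' @return `dir`, invisibly.
#' @export
write_network <- function(net, dir) {
  stopifnot(inherits(net, "supply_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edge <- function(M, dst_prefix = "") {
    idx <- which(M > 0, arr.ind = TRUE)
    data.frame(src_id = rownames(M)[idx[, 1]],
               dst_id = paste0(dst_prefix, colnames(M)[idx[, 2]]),
               prob = M[idx], stringsAsFactors = FALSE)
  }
  edges <- rbind(edge(net$P_Q), edge(net$P_R, "C:"))
  edges <- edges[order(edges$src_id, edges$dst_id), ]
  write_csv_raw(edges, file.path(dir, "edges.csv"))
  jsonlite::write_json(
    list(label = net$label, transient_ids = net$transient_ids,
         absorbing_ids = net$absorbing_ids, brand_ids = net$brand_ids,
         retailer_zone_ids = net$retailer_zone_ids),
    file.path(dir, "nodes.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a supply network written by [write_network()]
#'
#' @param dir directory with `edges.csv` and `nodes.json`.
#' @return A `supply_network`.
#' @export
read_network <- function(dir) {
  hdr <- jsonlite::read_json(file.path(dir, "nodes.json"),
                             simplifyVector = TRUE)
  edges <- read_csv_raw(file.path(dir, "edges.csv"),
                        c("src_id", "dst_id", "prob"), "edges")
  nt <- length(hdr$transient_ids)
  P_Q <- matrix(0, nt, nt, dimnames = list(hdr$transient_ids,
                                           hdr$transient_ids))
  P_R <- matrix(0, nt, length(hdr$absorbing_ids),
                dimnames = list(hdr$transient_ids, hdr$absorbing_ids))
  absorbing <- startsWith(edges$dst_id, "C:")
  qe <- edges[!absorbing, ]
  re <- edges[absorbing, ]
  P_Q[cbind(qe$src_id, qe$dst_id)] <- qe$prob
  P_R[cbind(re$src_id, sub("^C:", "", re$dst_id))] <- re$prob
  structure(list(transient_ids = hdr$transient_ids,
                 absorbing_ids = hdr$absorbing_ids,
                 brand_ids = hdr$brand_ids,
                 retailer_zone_ids = hdr$retailer_zone_ids,
                 P_Q = P_Q, P_R = P_R, label = hdr$label),
            class = "supply_network")
}

#' Write outbreaks to a long-format CSV
#'
#' One row per illness: `outbreak_id,true_source,zone_id,illness_index`.
#'
#' @param outbreaks list of `outbreak` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_outbreaks <- function(outbreaks, path) {
  rows <- do.call(rbind, lapply(seq_along(outbreaks), function(i) {
    ob <- outbreaks[[i]]
    data.frame(outbreak_id = i, true_source = ob$true_source,
               zone_id = ob$observations,
               illness_index = seq_along(ob$observations),
               stringsAsFactors = FALSE)
  }))
  write_csv_raw(rows, path)
  invisible(path)
}

#' Write a calibration report as JSON
#'
#' Records beta, iteration counts, the achieved mean trip distance and the
#' residual marginal error of a fitted gravity model.
#'
#' @param fit a [gravity_model()] fit.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(fit, path) {
  stopifnot(inherits(fit, "gravity_model"))
  jsonlite::write_json(
    list(beta = fit$beta, mean_distance_km = fit$mean_distance,
         target_mean_km = fit$target_mean_km,
         furness_iterations = fit$iterations,
         hyman_iterations = fit$outer_iterations,
         max_marginal_rel_error = fit$max_rel_error,
         converged = fit$converged),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys take the documented defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file; `NULL` returns the defaults.
#' @return Named list of validated configuration values.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(
    n_zones = 49L, n_brands = 10L, bbox_km = 30,
    pop_range = c(1000, 20000), stores_per_brand_range = c(5L, 20L),
    revenue_range = c(50e6, 500e6),
    target_mean_km = 4.65, intrazonal_method = "lattice",
    tol_km = 0.01, furness_tol = 1e-6,
    thresholds = c(0, 0.05, 0.10),
    scenarios = c(5, 10, 15, 20, 25, 30, 35, 40, 45, 49),
    n_outbreaks = 1000L, n_ill = 500L,
    illness_grid = c(1, 2, 5, 10, 20, 30, 50, 100), seed = 1L)
  if (is.null(path)) return(defaults)
  user <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("schema-error: unknown config key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cfg <- utils::modifyList(defaults, user)
  with(cfg, {
    if (n_zones < 2 || n_brands < 1 || n_outbreaks < 0 || n_ill < 1)
      stop("invalid-input: counts out of range in config", call. = FALSE)
    if (tol_km <= 0 || furness_tol <= 0 || target_mean_km <= 0)
      stop("invalid-input: tolerances must be positive", call. = FALSE)
    if (any(thresholds < 0) || any(thresholds >= 1))
      stop("invalid-input: thresholds must lie in [0, 1)", call. = FALSE)
  })
  cfg
}
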