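# Plain-text interchange: delimited time series, connectome CSV + JSON
# sidecar, toy-digraph edge lists, partition CSV, Betti-curve CSV/JSON.

#' Read regional time series from a delimited file
#'
#' Rows are time points, columns regions; an optional header row carries
#' region labels. Delimiter is inferred from the extension (`.csv` comma,
#' otherwise whitespace/tab).
#'
#' @param path file path.
#' @param header whether the first row holds region labels (default `TRUE`).
#' @return an [roi_timeseries].
#' @export
read_roi_timeseries <- function(path, header = TRUE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  df <- utils::read.table(path, header = header, sep = sep,
                          check.names = FALSE)
  roi_timeseries(as.matrix(df))
}

#' Write regional time series to CSV
#'
#' @param ts an [roi_timeseries].
#' @param path output path.
#' @export
write_roi_timeseries <- function(ts, path) {
  utils::write.csv(as.data.frame(ts$values), path, row.names = FALSE)
  invisible(path)
}

#' Write a connectome as CSV plus a JSON sidecar recording the lag
#'
#' @param conn a `directed_connectome`.
#' @param path CSV output path; the sidecar is `<path>.json`.
#' @export
write_connectome <- function(conn, path) {
  stopifnot(inherits(conn, "directed_connectome"))
  utils::write.csv(as.data.frame(conn$rho), path, row.names = TRUE)
  jsonlite::write_json(list(tau = conn$tau, region_ids = conn$region_ids),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a connectome written by [write_connectome()]
#'
#' @param path CSV path; if no sidecar exists, `tau` must be given.
#' @param tau lag override when the sidecar is absent.
#' @return a `directed_connectome`.
#' @export
read_connectome <- function(path, tau = NULL) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  rho <- as.matrix(df)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(tau)) tau <- meta$tau
  }
  if (is.null(tau)) stop("tau not recorded; pass it explicitly")
  structure(list(rho = clip_correlation(rho), tau = as.integer(tau),
                 region_ids = rownames(rho)),
            class = "directed_connectome")
}

#' Read a toy weighted digraph from an edge list
#'
#' Text lines `source target weight`; node labels are arbitrary strings and
#' the token `inf` (any case) marks an explicitly absent edge, which is
#' skipped.
#'
#' @param path edge-list file.
#' @return a [weighted_digraph].
#' @export
read_edgelist <- function(path) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("from", "to", "weight"),
                          colClasses = c("character", "character",
                                         "character"))
  w <- suppressWarnings(as.numeric(df$weight))
  w[tolower(df$weight) == "inf"] <- Inf
  if (anyNA(w)) stop("unparseable weight in edge list")
  keep <- is.finite(w)
  nodes <- sort(unique(c(df$from, df$to)))
  edges <- data.frame(from = match(df$from, nodes)[keep],
                      to = match(df$to, nodes)[keep],
                      weight = w[keep])
  weighted_digraph(length(nodes), edges, node_ids = nodes)
}

#' Read a region-to-subnetwork partition CSV
#'
#' Two columns: `region_label,subnetwork_label` (header optional but
#' recommended).
#'
#' @param path CSV path.
#' @return a [subnetwork_partition].
#' @export
read_partition <- function(path) {
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2) stop("partition file needs two columns")
  subnetwork_partition(df[, 1:2])
}

#' Write a partition CSV
#'
#' @param partition a [subnetwork_partition].
#' @param path output path.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(region_label = names(partition$mapping),
                   subnetwork_label = unname(partition$mapping))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write Betti curves of feature bundles as long-format CSV
#'
#' Columns: subject, subnetwork, n (homology degree), grid_index, threshold,
#' betti.
#'
#' @param bundles list of feature bundles.
#' @param path output CSV path.
#' @export
write_curves_csv <- function(bundles, path) {
  rows <- list()
  for (s in seq_along(bundles)) {
    for (cv in bundles[[s]]$curves) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, subnetwork = cv$subnetwork, n = cv$n,
        grid_index = seq_along(cv$values),
        threshold = cv$grid$points, betti = cv$values)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read long-format Betti-curve CSV back into per-subject value vectors
#'
#' Round-trips [write_curves_csv()]: values are returned per subject in the
#' canonical subnetwork/degree order used by `x_betti`.
#'
#' @param path CSV path.
#' @return list per subject of named list `x_betti`, plus attributes
#'   `subnetworks` and `T`.
#' @export
read_curves_csv <- function(path) {
  df <- utils::read.csv(path)
  subs <- sort(unique(df$subject))
  labs <- unique(df$subnetwork[order(df$n, match(df$subnetwork, SUBNETWORKS))])
  labs <- if (all(unique(df$subnetwork) %in% SUBNETWORKS)) {
    SUBNETWORKS[SUBNETWORKS %in% df$subnetwork]
  } else sort(unique(df$subnetwork))
  out <- lapply(subs, function(s) {
    d <- df[df$subject == s, ]
    v <- c()
    for (deg in 0:1) {
      for (lab in labs) {
        dd <- d[d$n == deg & d$subnetwork == lab, ]
        v <- c(v, dd$betti[order(dd$grid_index)])
      }
    }
    v
  })
  attr(out, "subnetworks") <- labs
  attr(out, "T") <- max(df$grid_index)
  out
}

#' Serialize a model checkpoint to JSON
#'
#' Single-file plain-text checkpoint: parameters, config and Betti-input
#' standardization statistics.
#'
#' @param model a fitted [bmh_net].
#' @param path output path.
#' @export
write_bmh_net <- function(model, path) {
  stopifnot(inherits(model, "bmh_net"))
  obj <- list(config = unclass(model$config),
              params = lapply(model$params, function(p) {
                if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
                else list(dim = NULL, data = as.vector(p))
              }),
              mu = model$mu, sd = model$sd,
              d_betti = model$d_betti, d_conn = model$d_conn,
              losses = model$losses, n_train = model$n_train,
              class_balance = model$class_balance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [write_bmh_net()]
#'
#' @param path checkpoint path.
#' @return a [bmh_net] object.
#' @export
read_bmh_net <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(p) {
    if (!is.null(p$dim) && length(p$dim)) {
      matrix(p$data, p$dim[1], p$dim[2])
    } else as.numeric(p$data)
  })
  cfg <- do.call(bmh_net_config, obj$config[names(formals(bmh_net_config))])
  structure(list(params = params, config = cfg, mu = obj$mu, sd = obj$sd,
                 d_betti = obj$d_betti, d_conn = obj$d_conn,
                 losses = obj$losses, n_train = obj$n_train,
                 class_balance = obj$class_balance),
            class = "bmh_net")
}
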