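#' Assemble a cure-model survival dataset from a data frame
#'
#' Splits the columns of a tabular right-censored survival dataset into the
#' four covariate blocks of a mixture cure frailty model: unpenalized and
#' penalized incidence covariates (`z_u`, `z_p`, acting on the probability of
#' being uncured) and unpenalized and penalized latency covariates
#' (`x_u`, `x_p`, acting on the event hazard of the uncured). The penalized
#' incidence and latency blocks may name the same columns (a shared
#' high-dimensional block, the usual situation with omics covariates).
#'
#' Character or factor columns assigned to `z_u` or `x_u` are dummy-encoded
#' deterministically: levels are sorted, the first level is the reference.
#'
#' @param data A data frame with one row per subject.
#' @param time Name of the observed-time column (strictly positive).
#' @param status Name of the event-indicator column (1 = event, 0 = censored).
#' @param z_u,z_p,x_u,x_p Character vectors of column names for the four
#'   covariate blocks. Any block may be empty (`character(0)`).
#' @param latent_cure,latent_frailty Optional column names carrying simulated
#'   latent truth (uncured indicator `y`, frailty `w`); used by evaluation
#'   metrics on synthetic data, never by the fitters.
#'
#' @return An object of class `cure_data`: a list with numeric vectors `time`,
#'   `event`, numeric matrices `z_u`, `z_p`, `x_u`, `x_p` (possibly
#'   zero-column), optional `latent_cure`/`latent_frailty`, and `n`.
#' @export
#' @examples
#' df <- tibble::tibble(t = rexp(20) + 0.1, d = rbinom(20, 1, 0.5),
#'                      age = rnorm(20), g1 = rnorm(20), g2 = rnorm(20))
#' cd <- cure_data(df, time = "t", status = "d", x_u = "age",
#'                 z_p = c("g1", "g2"), x_p = c("g1", "g2"))
cure_data <- function(data, time, status,
                      z_u = character(), z_p = character(),
                      x_u = character(), x_p = character(),
                      latent_cure = NULL, latent_frailty = NULL) {
  stopifnot(is.data.frame(data))
  need <- c(time, status, z_u, z_p, x_u, x_p, latent_cure, latent_frailty)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("columns not found in `data`: ",
                 paste(missing_cols, collapse = ", ")))
  }
  tm <- data[[time]]
  ev <- data[[status]]
  if (!is.numeric(tm) || anyNA(tm) || any(tm <= 0)) {
    abort(paste0("`", time, "` must be strictly positive and non-missing"))
  }
  if (anyNA(ev) || !all(ev %in% c(0, 1))) {
    abort(paste0("`", status, "` must contain only 0/1 values"))
  }

  out <- structure(
    list(time = as.numeric(tm), event = as.numeric(ev),
         z_u = encode_block(data, z_u, "z_u"),
         z_p = encode_block(data, z_p, "z_p", allow_factor = FALSE),
         x_u = encode_block(data, x_u, "x_u"),
         x_p = encode_block(data, x_p, "x_p", allow_factor = FALSE),
         n = nrow(data)),
    class = "cure_data")
  if (!is.null(latent_cure)) {
    y <- data[[latent_cure]]
    if (!all(y %in% c(0, 1))) abort("`latent_cure` must be 0/1")
    if (any(out$event == 1 & y == 0)) {
      abort("events recorded for latently cured subjects")
    }
    out$latent_cure <- as.numeric(y)
  }
  if (!is.null(latent_frailty)) {
    w <- data[[latent_frailty]]
    if (any(w <= 0)) abort("`latent_frailty` must be positive")
    out$latent_frailty <- as.numeric(w)
  }
  out
}

# dummy-encode a covariate block; sorted levels, first = reference
encode_block <- function(data, cols, label, allow_factor = TRUE) {
  if (!length(cols)) return(matrix(numeric(), nrow(data), 0))
  pieces <- lapply(cols, function(cl) {
    v <- data[[cl]]
    if (is.numeric(v)) {
      if (anyNA(v) || any(!is.finite(v))) {
        abort(paste0("non-finite values in column `", cl, "` (", label, ")"))
      }
      m <- matrix(as.numeric(v), ncol = 1)
      colnames(m) <- cl
      return(m)
    }
    if (!allow_factor) {
      abort(paste0("penalized block ", label, " requires numeric columns; `",
                   cl, "` is not numeric"))
    }
    lev <- sort(unique(as.character(v)))
    if (length(lev) < 2) {
      m <- matrix(0, length(v), 0)
      return(m)
    }
    m <- sapply(lev[-1], function(l) as.numeric(as.character(v) == l))
    m <- matrix(m, nrow = length(v))
    colnames(m) <- paste0(cl, lev[-1])
    m
  })
  do.call(cbind, pieces)
}

#' @export
print.cure_data <- function(x, ...) {
  cat("<cure_data> n =", x$n,
      " events =", sum(x$event),
      sprintf(" (censoring %.1f%%)", 100 * mean(1 - x$event)), "\n")
  cat("  incidence covariates: ", ncol(x$z_u), " unpenalized + ",
      ncol(x$z_p), " penalized\n", sep = "")
  cat("  latency covariates:   ", ncol(x$x_u), " unpenalized + ",
      ncol(x$x_p), " penalized\n", sep = "")
  if (!is.null(x$latent_cure)) {
    cat(sprintf("  latent truth present (cured %.1f%%)\n",
                100 * mean(1 - x$latent_cure)))
  }
  invisible(x)
}

#' Read a cure-model dataset from CSV with a column-role manifest
#'
#' @param path Path to a CSV file with one row per subject.
#' @param manifest A named list mapping roles `time`, `status` (single column
#'   names) and `z_u`, `z_p`, `x_u`, `x_p` (character vectors, may be missing
#'   or empty) to columns of the file. `z_p` and `x_p` may list the same
#'   columns (shared penalized block). Optional roles `latent_cure`,
#'   `latent_frailty`, `id`. Every non-id column must be assigned a role.
#' @return A [cure_data] object.
#' @export
read_cure_data <- function(path, manifest) {
  df <- utils::read.csv(path, check.names = FALSE)
  roles <- c("time", "status", "z_u", "z_p", "x_u", "x_p",
             "latent_cure", "latent_frailty", "id")
  bad <- setdiff(names(manifest), roles)
  if (length(bad)) abort(paste0("unknown manifest roles: ", paste(bad, collapse = ", ")))
  if (is.null(manifest$time) || is.null(manifest$status)) {
    abort("manifest must assign `time` and `status` columns")
  }
  assigned <- unique(unlist(manifest))
  unassigned <- setdiff(names(df), assigned)
  if (length(unassigned)) {
    abort(paste0("columns without a manifest role: ",
                 paste(unassigned, collapse = ", ")))
  }
  cure_data(df, time = manifest$time, status = manifest$status,
            z_u = manifest$z_u %||% character(),
            z_p = manifest$z_p %||% character(),
            x_u = manifest$x_u %||% character(),
            x_p = manifest$x_p %||% character(),
            latent_cure = manifest$latent_cure,
            latent_frailty = manifest$latent_frailty)
}

#' Write a cure-model dataset to CSV
#'
#' Writes one row per subject with `id`, `time`, `status`, the covariate
#' blocks, and latent-truth columns when present. Shared penalized columns
#' (identical `z_p`/`x_p`) are written once.
#'
#' @param data A [cure_data] object.
#' @param path Output CSV path.
#' @return `path`, invisibly. The matching manifest is attached as the
#'   `"manifest"` attribute of the return value.
#' @export
write_cure_data <- function(data, path) {
  stopifnot(inherits(data, "cure_data"))
  shared <- ncol(data$z_p) == ncol(data$x_p) && ncol(data$z_p) > 0 &&
    identical(unname(data$z_p), unname(data$x_p))
  df <- data.frame(id = seq_len(data$n), time = data$time, status = data$event)
  manifest <- list(id = "id", time = "time", status = "status")
  add_block <- function(df, m, prefix) {
    if (!ncol(m)) return(list(df = df, cols = character()))
    cols <- colnames(m)
    if (is.null(cols)) cols <- paste0(prefix, seq_len(ncol(m)))
    colnames(m) <- cols
    list(df = cbind(df, as.data.frame(m)), cols = cols)
  }
  a <- add_block(df, data$z_u, "zu"); df <- a$df; manifest$z_u <- a$cols
  a <- add_block(df, data$x_u, "xu"); df <- a$df; manifest$x_u <- a$cols
  if (shared) {
    a <- add_block(df, data$z_p, "p"); df <- a$df
    manifest$z_p <- a$cols; manifest$x_p <- a$cols
  } else {
    a <- add_block(df, data$z_p, "zp"); df <- a$df; manifest$z_p <- a$cols
    a <- add_block(df, data$x_p, "xp"); df <- a$df; manifest$x_p <- a$cols
  }
  if (!is.null(data$latent_cure)) {
    df$latent_cure <- data$latent_cure
    manifest$latent_cure <- "latent_cure"
  }
  if (!is.null(data$latent_frailty)) {
    df$latent_frailty <- data$latent_frailty
    manifest$latent_frailty <- "latent_frailty"
  }
  # full-precision doubles so the file round-trips bit-identically
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(structure(path, manifest = manifest))
}

#' Convert a cure-model dataset to a tibble
#'
#' @param x A [cure_data] object.
#' @param ... Unused.
#' @return A tibble with `time`, `status`, covariate columns and any latent
#'   truth columns. Shared penalized columns are emitted once.
#' @importFrom tibble as_tibble
#' @export
as_tibble.cure_data <- function(x, ...) {
  shared <- ncol(x$z_p) == ncol(x$x_p) && ncol(x$z_p) > 0 &&
    identical(unname(x$z_p), unname(x$x_p))
  named <- function(m, prefix) {
    if (!ncol(m)) return(NULL)
    if (is.null(colnames(m))) colnames(m) <- paste0(prefix, seq_len(ncol(m)))
    tibble::as_tibble(m)
  }
  out <- tibble::tibble(time = x$time, status = x$event)
  blocks <- c(list(named(x$z_u, "zu"), named(x$x_u, "xu")),
              if (shared) list(named(x$z_p, "p"))
              else list(named(x$z_p, "zp"), named(x$x_p, "xp")))
  for (b in blocks) if (!is.null(b)) out <- dplyr::bind_cols(out, b)
  if (!is.null(x$latent_cure)) out$latent_cure <- x$latent_cure
  if (!is.null(x$latent_frailty)) out$latent_frailty <- x$latent_frailty
  out
}
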