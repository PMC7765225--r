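#' The four excited-state classes
#'
#' @return character vector: monomer, exciton, excimer, charge_transfer.
#' @export
state_classes <- function() {
  c("monomer", "exciton", "excimer", "charge_transfer")
}

#' Classification thresholds for DL_av and CTN
#'
#' Defaults are the literature thresholds: monomer-like states have
#' DL_av < 1.25 and CTN < 0.2; excitons DL_av > 1.25 and CTN < 0.2;
#' excimers 0.2 <= CTN <= 0.8; charge-transfer states CTN > 0.8.
#'
#' @param dl_cut delocalization-length cut separating monomer from exciton
#'   (default 1.25; must exceed 1).
#' @param ctn_low,ctn_high charge-transfer-number cuts (defaults 0.2, 0.8;
#'   0 < ctn_low < ctn_high < 1).
#' @return list of class `class_thresholds`.
#' @export
class_thresholds <- function(dl_cut = 1.25, ctn_low = 0.2, ctn_high = 0.8) {
  if (!(dl_cut > 1)) stop("dl_cut must exceed 1", call. = FALSE)
  if (!(ctn_low > 0 && ctn_low < ctn_high && ctn_high < 1))
    stop("need 0 < ctn_low < ctn_high < 1", call. = FALSE)
  structure(list(dl_cut = dl_cut, ctn_low = ctn_low, ctn_high = ctn_high),
            class = "class_thresholds")
}

#' Normalize a fragment Omega matrix
#'
#' The Omega matrix partitions the transition density over fragments:
#' element (A, B) is the weight with the hole on fragment A and the excited
#' electron on fragment B. Descriptors are fractions of the total weight, so
#' the matrix is normalized to unit element sum; the pre-normalization sum
#' is kept as attribute `raw_norm`.
#'
#' @param raw square numeric matrix with nonnegative entries, at least one
#'   positive, N >= 2 fragments.
#' @return the normalized matrix with attribute `raw_norm`.
#' @examples
#' normalize_omega(matrix(c(2, 0, 0, 0), 2, 2))
#' @export
normalize_omega <- function(raw) {
  raw <- as.matrix(raw)
  if (nrow(raw) != ncol(raw) || nrow(raw) < 2)
    stop("Omega must be a square matrix with at least 2 fragments",
         call. = FALSE)
  if (any(!is.finite(raw)) || any(raw < 0))
    stop("Omega elements must be finite and nonnegative", call. = FALSE)
  tot <- sum(raw)
  if (tot <= 0) stop("Omega matrix is all zero", call. = FALSE)
  om <- raw / tot
  attr(om, "raw_norm") <- tot
  om
}

.check_omega <- function(om) {
  if (abs(sum(om) - 1) > 1e-8)
    stop("Omega matrix is not normalized; call normalize_omega() first",
         call. = FALSE)
  om
}

#' Hole and electron fragment populations
#'
#' Row sums of the normalized Omega matrix give the hole population per
#' fragment; column sums give the excited-electron population. Each sums
#' to 1.
#'
#' @param om normalized Omega matrix (see [normalize_omega()]).
#' @return numeric vector of per-fragment weights.
#' @export
hole_populations <- function(om) rowSums(.check_omega(om))

#' @rdname hole_populations
#' @export
electron_populations <- function(om) colSums(.check_omega(om))

#' Participation ratio of a fragment population
#'
#' `PR = 1 / sum(p^2)`: the effective number of fragments over which the
#' hole or electron is spread; 1 when fully localized, N when uniform over
#' N fragments.
#'
#' @param pops per-fragment weights summing to 1.
#' @return scalar in \[1, N\].
#' @export
participation_ratio <- function(pops) {
  if (abs(sum(pops) - 1) > 1e-8 || any(pops < -1e-12))
    stop("populations must be nonnegative and sum to 1", call. = FALSE)
  1 / sum(pops^2)
}

#' Average delocalization length DL_av
#'
#' Arithmetic mean of the hole and electron participation ratios: 1 for a
#' pure monomer state, 2 for a pure exciton delocalized over two fragments.
#'
#' @inheritParams hole_populations
#' @return scalar in \[1, N\].
#' @export
dl_av <- function(om) {
  om <- .check_omega(om)
  (participation_ratio(rowSums(om)) +
     participation_ratio(colSums(om))) / 2
}

#' Charge-transfer number CTN
#'
#' Fraction of transition-density weight with hole and electron on
#' different fragments (sum of off-diagonal Omega elements): 0 for pure
#' Frenkel excitons and monomers, 1 for pure charge-transfer states.
#'
#' @inheritParams hole_populations
#' @return scalar in \[0, 1\].
#' @export
ctn <- function(om) {
  om <- .check_omega(om)
  sum(om) - sum(diag(om))
}

#' Population-weighted fragment position (POS)
#'
#' `sum(A * p_A)` over fragment indices A = 1..N: the mean fragment index
#' of the hole (POS_i, from hole populations) or the excited electron
#' (POS_f, from electron populations).
#'
#' @inheritParams participation_ratio
#' @return scalar in \[1, N\].
#' @export
pos <- function(pops) {
  if (abs(sum(pops) - 1) > 1e-8 || any(pops < -1e-12))
    stop("populations must be nonnegative and sum to 1", call. = FALSE)
  sum(seq_along(pops) * pops)
}

#' Classify excited states from DL_av and CTN
#'
#' CTN above `ctn_high` takes precedence (charge transfer); otherwise CTN
#' below `ctn_low` splits into monomer (DL_av strictly below `dl_cut`) and
#' exciton; everything with intermediate CTN (inclusive bounds) is an
#' excimer, including the low-DL_av/intermediate-CTN corner. The mapping is
#' total: every in-range (DL_av, CTN) pair gets exactly one label.
#'
#' @param dl,ct numeric vectors of DL_av (>= 1) and CTN (in \[0, 1\]).
#' @param thresholds a [class_thresholds()].
#' @return character vector of class labels (see [state_classes()]).
#' @examples
#' classify_state(c(1.0, 1.5, 1.05), c(0.0, 0.5, 0.95))
#' @export
classify_state <- function(dl, ct, thresholds = class_thresholds()) {
  if (length(dl) != length(ct))
    stop("dl and ct must have equal length", call. = FALSE)
  if (any(dl < 1 - 1e-9) || any(ct < -1e-9) || any(ct > 1 + 1e-9))
    stop("descriptors out of range: need DL_av >= 1 and CTN in [0, 1]",
         call. = FALSE)
  th <- thresholds
  ifelse(ct > th$ctn_high, "charge_transfer",
         ifelse(ct < th$ctn_low,
                ifelse(dl < th$dl_cut, "monomer", "exciton"),
                "excimer"))
}

#' All transition-density descriptors for one state
#'
#' @param om normalized Omega matrix.
#' @param thresholds a [class_thresholds()].
#' @return list with `hole_pops`, `elec_pops`, `pr_hole`, `pr_elec`,
#'   `dl_av`, `ctn`, `pos_i`, `pos_f`, `class`.
#' @export
state_descriptors <- function(om, thresholds = class_thresholds()) {
  om <- .check_omega(om)
  hp <- rowSums(om)
  ep <- colSums(om)
  prh <- participation_ratio(hp)
  pre <- participation_ratio(ep)
  dl <- (prh + pre) / 2
  ct <- sum(om) - sum(diag(om))
  list(hole_pops = hp, elec_pops = ep, pr_hole = prh, pr_elec = pre,
       dl_av = dl, ctn = ct, pos_i = pos(hp), pos_f = pos(ep),
       class = classify_state(dl, ct, thresholds))
}

.omega_cols <- function(n_frag) {
  idx <- expand.grid(B = seq_len(n_frag), A = seq_len(n_frag))
  sprintf("om_%d_%d", idx$A, idx$B)  # row-major: om_1_1 om_1_2 om_2_1 ...
}

.detect_n_frag <- function(cols) {
  om_cols <- grep("^om_[0-9]+_[0-9]+$", cols, value = TRUE)
  if (!length(om_cols))
    stop("no Omega columns (om_A_B) found", call. = FALSE)
  n <- max(as.integer(unlist(regmatches(om_cols,
                                        gregexpr("[0-9]+", om_cols)))))
  missing <- setdiff(.omega_cols(n), om_cols)
  if (length(missing))
    stop("incomplete Omega columns; missing ",
         paste(missing, collapse = ", "), call. = FALSE)
  n
}

#' Characterize an ensemble of excited-state records
#'
#' Computes the full descriptor set and class label for each state record.
#' Malformed records (e.g. all-zero or negative Omega) are flagged in the
#' `status` column with NA descriptors; the run continues.
#'
#' @param records data.frame of state records with columns `frame`, `state`,
#'   `energy_ev`, `osc`, Omega columns `om_A_B` (row-major), optional
#'   `model` (see [read_state_table()]).
#' @param thresholds a [class_thresholds()].
#' @return data.frame with identifier columns, per-fragment `hole_A` /
#'   `elec_A` populations, `pr_hole`, `pr_elec`, `dl_av`, `ctn`, `pos_i`,
#'   `pos_f`, `class`, `status`; attribute `n_frag` records the fragment
#'   count.
#' @export
analyze_records <- function(records, thresholds = class_thresholds()) {
  req <- c("frame", "state", "energy_ev", "osc")
  missing <- setdiff(req, names(records))
  if (length(missing))
    stop("records are missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  has_model <- "model" %in% names(records)
  nr <- nrow(records)
  if (nr == 0) {
    n_frag <- tryCatch(.detect_n_frag(names(records)), error = function(e) 2L)
  } else {
    n_frag <- .detect_n_frag(names(records))
  }
  oc <- .omega_cols(n_frag)
  hole_nm <- sprintf("hole_%d", seq_len(n_frag))
  elec_nm <- sprintf("elec_%d", seq_len(n_frag))
  desc_nm <- c("pr_hole", "pr_elec", "dl_av", "ctn", "pos_i", "pos_f")
  num <- matrix(NA_real_, nr, 2 * n_frag + length(desc_nm),
                dimnames = list(NULL, c(hole_nm, elec_nm, desc_nm)))
  cls <- rep(NA_character_, nr)
  status <- rep("ok", nr)
  if (nr > 0) {
    omall <- as.matrix(records[, oc, drop = FALSE])
    for (i in seq_len(nr)) {
      res <- tryCatch({
        raw <- matrix(omall[i, ], n_frag, n_frag, byrow = TRUE)
        d <- state_descriptors(normalize_omega(raw), thresholds)
        num[i, ] <- c(d$hole_pops, d$elec_pops, d$pr_hole, d$pr_elec,
                      d$dl_av, d$ctn, d$pos_i, d$pos_f)
        cls[i] <- d$class
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(res)) status[i] <- res
    }
  }
  out <- data.frame(frame = records$frame, state = records$state,
                    energy_ev = records$energy_ev, osc = records$osc,
                    stringsAsFactors = FALSE)
  if (has_model) out$model <- records$model
  out <- cbind(out, as.data.frame(num))
  out$class <- cls
  out$status <- status
  attr(out, "n_frag") <- n_frag
  out
}

#' Read / write the excited-state table (TSV)
#'
#' The dialect is a UTF-8 tab-separated table with header
#' `frame state energy_ev osc om_1_1 om_1_2 om_2_1 om_2_2` (row-major Omega
#' expansion for more fragments) and an optional trailing `model` column;
#' '.' is the decimal separator. Parse errors name the offending line.
#'
#' @param path file path.
#' @param records data.frame of state records (writer).
#' @return data.frame of state records (reader) or `path` (writer).
#' @export
read_state_table <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty state table: ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  req <- c("frame", "state", "energy_ev", "osc")
  missing <- setdiff(req, header)
  if (length(missing))
    stop("state table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  n_frag <- .detect_n_frag(header)
  oc <- .omega_cols(n_frag)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  cols <- c(req, oc, intersect("model", header))
  if (!length(body)) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    if ("model" %in% cols) df$model <- character(0)
    return(df)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(header))
  if (length(bad))
    stop("state table ", path, ": line ", bad[1] + 1L, " has ",
         lengths(fields)[bad[1]], " fields, expected ", length(header),
         call. = FALSE)
  mat <- do.call(rbind, fields)
  colnames(mat) <- header
  df <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                   matrix(nrow = length(body), ncol = 0))
  for (cn in c(req, oc)) {
    v <- suppressWarnings(as.numeric(mat[, cn]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("state table ", path, ": non-numeric value in column '", cn,
           "' at line ", bad + 1L, call. = FALSE)
    }
    df[[cn]] <- v
  }
  for (cn in oc) {
    if (any(df[[cn]] < 0)) {
      bad <- which(df[[cn]] < 0)[1]
      stop("state table ", path, ": negative Omega element in column '", cn,
           "' at line ", bad + 1L, call. = FALSE)
    }
  }
  if ("model" %in% header) df$model <- mat[, "model"]
  df
}

#' @rdname read_state_table
#' @export
write_state_table <- function(records, path) {
  num <- vapply(records, is.numeric, logical(1))
  out <- records
  out[num] <- lapply(records[num], function(x) sprintf("%.17g", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
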