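#' Read, validate and write NONMEM-style PK datasets
#'
#' The interchange format is a CSV with one row per dose or observation event:
#' \describe{
#'   \item{`ID`}{Subject identifier.}
#'   \item{`TIME`}{Hours since birth, non-negative, sorted within subject.}
#'   \item{`EVID`}{1 for dose rows, 0 for observation rows.}
#'   \item{`AMT`}{Dose amount, mg (dose rows; 0/NA otherwise).}
#'   \item{`DUR`}{Infusion duration, h (dose rows). A `RATE` column (mg/h) is
#'     accepted instead and converted.}
#'   \item{`DV`}{Observed concentration, mg/L (observation rows).}
#'   \item{`MDV`}{Missing-DV flag; optional, defaults to `1 - (EVID == 0)`.}
#'   \item{`GA`, `BW`, `PNA`}{Covariates: gestational age (weeks), birth
#'     weight (kg), postnatal age at the record time (days).}
#' }
#'
#' @param path CSV file path.
#' @return A validated `pk_dataset` data frame.
#' @export
read_pk_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset not found: ", path, call. = FALSE)
  d <- utils::read.csv(path)
  validate_pk_dataset(d)
}

#' @rdname read_pk_dataset
#' @param data A data frame in the format above.
#' @export
validate_pk_dataset <- function(data) {
  problems <- character(0)
  need <- c("ID", "TIME", "EVID")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("dataset missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"DUR" %in% names(data)) {
    if ("RATE" %in% names(data)) {
      data$DUR <- ifelse(data$EVID == 1, data$AMT / data$RATE, NA_real_)
    } else if (any(data$EVID == 1)) {
      stop("dataset needs a DUR or RATE column for dose rows", call. = FALSE)
    }
  }
  if (!"MDV" %in% names(data)) data$MDV <- as.integer(data$EVID != 0)

  note <- function(rows, msg) {
    if (length(rows)) {
      problems <<- c(problems, sprintf("row %d: %s", rows, msg))
    }
  }
  note(which(data$TIME < 0), "negative TIME")
  note(which(data$EVID == 1 & (is.na(data$AMT) | data$AMT <= 0)),
       "dose row with missing/non-positive AMT")
  note(which(data$EVID == 1 & (is.na(data$DUR) | data$DUR <= 0)),
       "dose row with missing/non-positive DUR")
  note(which(data$EVID == 0 & data$MDV == 0 & (is.na(data$DV) | data$DV < 0)),
       "observation row with missing/negative DV")

  for (id in unique(data$ID)) {
    rows <- which(data$ID == id)
    tt <- data$TIME[rows]
    if (is.unsorted(tt)) {
      problems <- c(problems, sprintf("subject %s: TIME not sorted", id))
    }
    obs <- rows[data$EVID[rows] == 0 & data$MDV[rows] == 0]
    doses <- rows[data$EVID[rows] == 1]
    if (length(obs) && (!length(doses) ||
                        min(data$TIME[doses]) > min(data$TIME[obs]))) {
      problems <- c(problems,
                    sprintf("subject %s: observation before any dose", id))
    }
  }
  if (length(problems)) {
    stop("invalid PK dataset:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  class(data) <- c("pk_dataset", "data.frame")
  data
}

#' @rdname read_pk_dataset
#' @export
write_pk_dataset <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Internal: split a dataset into per-subject structures used by the
# evaluation functions.
.split_subjects <- function(data) {
  lapply(split(seq_len(nrow(data)), data$ID)[as.character(unique(data$ID))],
         function(rows) {
    d <- data[rows, , drop = FALSE]
    doses <- d[d$EVID == 1, , drop = FALSE]
    obs <- d[d$EVID == 0 & d$MDV == 0, , drop = FALSE]
    first <- d[1, ]
    list(
      id = first$ID,
      # covariates at the record level; pna0 back-calculated so PNA(t) lines up
      subject = list(id = first$ID, GA = first$GA, birth_weight = first$BW,
                     pna0 = if (!is.null(first$PNA)) first$PNA - first$TIME / 24 else 0),
      doses = doses, obs = obs
    )
  })
}

# Internal: schedule + per-dose-parameter events for one subject
.subject_events <- function(sub, model, eta = NULL) {
  lapply(seq_len(nrow(sub$doses)), function(i) {
    d <- sub$doses[i, ]
    subj <- sub$subject
    subj$GA <- d$GA %||% subj$GA
    subj$birth_weight <- d$BW %||% subj$birth_weight
    list(start_time = d$TIME, amount = d$AMT, duration = d$DUR,
         params = individual_parameters(subj, model, eta = eta, time = d$TIME))
  })
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
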