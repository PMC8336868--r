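#' The 19-channel 10-20 montage
#'
#' Canonical channel ordering, hemisphere/midline partition, the
#' task-to-contralateral-channel map used for Mu-suppression scoring, and
#' approximate 2-D scalp coordinates (unit head radius, x toward the right
#' ear, y toward the nasion).
#'
#' The older temporal labels T3/T4/T5/T6 are canonical here; readers
#' normalize the modern spellings (T7/T8/P7/P8) to these.
#'
#' @return An object of class `mi_montage`: a list with elements
#'   `channels` (ordered labels), `left_set`, `right_set`, `medial_set`,
#'   `contralateral` (named map `left`/`right` -> channel), `ipsilateral`,
#'   and `coords` (tibble with `channel`, `x`, `y`).
#' @examples
#' m <- mi_montage()
#' m$contralateral[["left"]] # C4
#' @export
mi_montage <- function() {
  channels <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3",
                "Cz", "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
  left_set <- c("Fp1", "F7", "F3", "T3", "C3", "T5", "P3", "O1")
  right_set <- c("Fp2", "F8", "F4", "T4", "C4", "T6", "P4", "O2")
  medial_set <- c("Fz", "Cz", "Pz")
  coords <- tibble::tribble(
    ~channel, ~x, ~y,
    "Fp1", -0.31,  0.95,
    "Fp2",  0.31,  0.95,
    "F7",  -0.81,  0.59,
    "F3",  -0.55,  0.48,
    "Fz",   0.00,  0.50,
    "F4",   0.55,  0.48,
    "F8",   0.81,  0.59,
    "T3",  -1.00,  0.00,
    "C3",  -0.50,  0.00,
    "Cz",   0.00,  0.00,
    "C4",   0.50,  0.00,
    "T4",   1.00,  0.00,
    "T5",  -0.81, -0.59,
    "P3",  -0.55, -0.48,
    "Pz",   0.00, -0.50,
    "P4",   0.55, -0.48,
    "T6",   0.81, -0.59,
    "O1",  -0.31, -0.95,
    "O2",   0.31, -0.95
  )
  m <- structure(
    list(
      channels = channels,
      left_set = left_set,
      right_set = right_set,
      medial_set = medial_set,
      contralateral = c(left = "C4", right = "C3"),
      ipsilateral = c(left = "C3", right = "C4"),
      coords = coords[match(channels, coords$channel), ]
    ),
    class = "mi_montage"
  )
  validate_montage(m)
  m
}

validate_montage <- function(m) {
  parts <- c(m$left_set, m$right_set, m$medial_set)
  if (length(parts) != length(m$channels) || anyDuplicated(parts) ||
      !setequal(parts, m$channels)) {
    stop("montage hemisphere/midline sets must partition the channel list",
         call. = FALSE)
  }
  if (!identical(sort(unname(m$contralateral)), c("C3", "C4"))) {
    stop("contralateral map must point at the C3/C4 mirror pair", call. = FALSE)
  }
  invisible(m)
}

#' @export
print.mi_montage <- function(x, ...) {
  cat("<mi_montage> 19-channel 10-20 montage\n")
  cat("  channels:", paste(x$channels, collapse = " "), "\n")
  cat("  contralateral: left-MI ->", x$contralateral[["left"]],
      ", right-MI ->", x$contralateral[["right"]], "\n")
  invisible(x)
}

#' Contralateral / ipsilateral channel for a task label
#'
#' @param task character vector of task labels, `"left"` or `"right"`.
#' @param role `"contra"` (hemisphere opposite the imagined hand) or `"ipsi"`.
#' @param montage an [mi_montage()].
#' @return Channel labels, same length as `task`.
#' @examples
#' role_channel(c("left", "right"), "contra") # "C4" "C3"
#' @export
role_channel <- function(task, role = c("contra", "ipsi"), montage = mi_montage()) {
  role <- match.arg(role)
  if (!all(task %in% c("left", "right"))) {
    stop("role_channel() is defined for left/right MI tasks only", call. = FALSE)
  }
  map <- if (role == "contra") montage$contralateral else montage$ipsilateral
  unname(map[task])
}

# Normalize EDF-style channel labels to canonical montage spelling:
# strips "EEG " prefixes and reference suffixes ("-REF", "-A1", ...), fixes
# case, and maps modern temporal labels onto the older 10-20 names.
normalize_channel_labels <- function(labels) {
  x <- trimws(labels)
  x <- sub("^EEG[ _]*", "", x, ignore.case = TRUE)
  x <- sub("[-_ ](REF|LE|A1|A2|AVG|M1|M2).*$", "", x, ignore.case = TRUE)
  canon <- mi_montage()$channels
  idx <- match(toupper(x), toupper(canon))
  out <- ifelse(is.na(idx), x, canon[idx])
  modern <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")
  hit <- toupper(out) %in% names(modern)
  out[hit] <- unname(modern[toupper(out)[hit]])
  out
}
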