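#' INTER-NDA item map
#'
#' An item map declares, for each of the instrument's items, its identifier,
#' the developmental domain it scores, and whether it is rated on a 3-point
#' or 5-point ordinal scale. The packaged default distributes the 37 items of
#' the instrument across the six domains (12 cognitive, 8 language, 4 fine
#' motor, 4 gross motor, 5 positive behaviour, 4 negative behaviour), with 30
#' five-point and 6 three-point items; the one item whose scale the
#' instrument documentation leaves unstated is treated as five-point. The
#' domain allocation is a package convention: item-to-domain assignment is
#' configuration, not code, and any mapping can be supplied instead.
#'
#' @param items Optional data frame with columns `item_id`, `domain`,
#'   `scale_points` (and optionally `admin_mode`). When `NULL`, the packaged
#'   default 37-item map is returned.
#' @param version Version tag stored on the map.
#'
#' @return A tibble of class `nda_item_map` with columns `item_id`, `domain`,
#'   `scale_points`, `admin_mode`.
#'
#' @examples
#' nda_item_map()
#' nda_item_map(data.frame(item_id = "c1", domain = "cognitive",
#'                         scale_points = 5))
#' @export
nda_item_map <- function(items = NULL, version = "default-37") {
  if (is.null(items)) {
    items <- default_item_table()
    version <- "default-37"
  }
  items <- tibble::as_tibble(items)
  required <- c("item_id", "domain", "scale_points")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0) {
    abort(paste0("item map lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"admin_mode" %in% names(items)) items$admin_mode <- "direct"
  items$item_id <- as.character(items$item_id)
  items$scale_points <- as.integer(items$scale_points)

  if (anyDuplicated(items$item_id)) {
    abort(paste0("duplicate item_id in item map: ",
                 paste(unique(items$item_id[duplicated(items$item_id)]),
                       collapse = ", ")))
  }
  bad_dom <- setdiff(unique(items$domain), NDA_DOMAINS)
  if (length(bad_dom) > 0) {
    abort(paste0("unknown domain(s): ", paste(bad_dom, collapse = ", ")))
  }
  if (!all(items$scale_points %in% c(3L, 5L))) {
    abort("scale_points must be 3 or 5 for every item")
  }
  bad_mode <- setdiff(unique(items$admin_mode),
                      c("direct", "observation", "caregiver_report"))
  if (length(bad_mode) > 0) {
    abort(paste0("unknown admin_mode(s): ", paste(bad_mode, collapse = ", ")))
  }
  structure(items, class = c("nda_item_map", class(items)),
            version = version)
}

# Default allocation of 37 items: 31 five-point + 6 three-point.
# Three-point items sit in the motor and negative-behaviour domains, where
# pass/emerging/fail style ratings are typical for directly-observed skills.
default_item_table <- function() {
  spec <- list(
    cognitive          = list(n = 12, three = 0, mode = "direct"),
    language           = list(n = 8,  three = 0, mode = "direct"),
    fine_motor         = list(n = 4,  three = 2, mode = "direct"),
    gross_motor        = list(n = 4,  three = 2, mode = "observation"),
    positive_behaviour = list(n = 5,  three = 0, mode = "observation"),
    negative_behaviour = list(n = 4,  three = 2, mode = "caregiver_report")
  )
  purrr::imap_dfr(spec, function(s, dom) {
    prefix <- c(cognitive = "cog", language = "lan", fine_motor = "fmo",
                gross_motor = "gmo", positive_behaviour = "pbe",
                negative_behaviour = "nbe")[[dom]]
    tibble::tibble(
      item_id = sprintf("%s%02d", prefix, seq_len(s$n)),
      domain = dom,
      scale_points = c(rep(5L, s$n - s$three), rep(3L, s$three)),
      admin_mode = s$mode
    )
  })
}

#' Read an item map from a config file
#'
#' The file is CSV with columns `item_id`, `domain`, `scale_points` and
#' optionally `admin_mode`, one row per item.
#'
#' @param path Path to the CSV config.
#' @return An `nda_item_map` (see [nda_item_map()]).
#' @export
read_item_map <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  nda_item_map(df, version = basename(path))
}
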