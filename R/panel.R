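#' Canonical channel order
#'
#' Every event matrix in the package uses the fixed column order
#' forward scatter, side scatter, then the five fluorescence channels.
#' All downstream feature indices refer to this order.
#'
#' @return Character vector of the seven channel names.
#' @export
flow_channels <- function() {
  c("FS", "SS", "FL1", "FL2", "FL3", "FL4", "FL5")
}

# Marker panel of the seven informative tubes. FL3 is CD45-ECD in every
# tube; tube 8 is an isotype control and never modelled.
.panel_table <- function() {
  data.frame(
    tube = 1:7,
    FL1 = c("IgG1-FITC", "Kappa-FIT", "CD7-FITC", "CD15-FITC",
            "CD14-FITC", "HLA-DR-FITC", "CD5-FITC"),
    FL2 = c("IgG1-PE", "Lambda-PE", "CD4-PE", "CD13-PE",
            "CD11c-PE", "CD117-PE", "CD19-PE"),
    FL3 = rep("CD45-ECD", 7),
    FL4 = c("IgG1-PC5", "CD19-PC5", "CD8-PC5", "CD16-PC5",
            "CD64-PC5", "CD34-PC5", "CD3-PC5"),
    FL5 = c("IgG1-PC7", "CD20-PC7", "CD2-PC7", "CD56-PC7",
            "CD33-PC7", "CD38-PC7", "CD10-PC7"),
    stringsAsFactors = FALSE
  )
}

#' Marker panel of the seven informative tubes
#'
#' Returns the antibody-fluorochrome panel measured in each tube: one row
#' per tube, columns `FL1`..`FL5`.  CD45-ECD occupies FL3 in every tube so
#' that the major leukocyte populations can be located in any aliquot.
#'
#' @return A `data.frame` with columns `tube`, `FL1`..`FL5`.
#' @export
#' @examples
#' aml_panel()
aml_panel <- function() {
  .panel_table()
}

#' Look up the marker measured on a channel of a tube
#'
#' @param tube_id Integer tube number in 1..7.  The control tube (8) is not
#'   part of the informative panel and is rejected.
#' @param channel One of `"FS"`, `"SS"`, `"FL1"`..`"FL5"`.  Scatter
#'   channels carry no antibody and return their own name.
#' @return The marker label, e.g. `panel_lookup(6, "FL4")` is
#'   `"CD34-PC5"`.
#' @export
panel_lookup <- function(tube_id, channel) {
  if (length(tube_id) != 1L || !tube_id %in% 1:7) {
    stop("`tube_id` must be a single integer in 1..7 (tube 8 is the ",
         "non-informative control tube)", call. = FALSE)
  }
  channel <- as.character(channel)
  if (length(channel) != 1L || !channel %in% flow_channels()) {
    stop("unknown channel: ", channel, call. = FALSE)
  }
  if (channel %in% c("FS", "SS")) {
    return(channel)
  }
  .panel_table()[[channel]][tube_id]
}

# "CD34-PC5_6"-style label for a per-tube feature.
.marker_label <- function(tube_id, channel) {
  paste0(panel_lookup(tube_id, channel), "_", tube_id)
}
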