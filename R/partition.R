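#' Construct a network partition
#'
#' @param labels character or factor vector of network labels, one per
#'   component; names are component ids (generated as IC01, IC02, ... when
#'   absent).
#' @return a [NetworkPartition-class].
#' @examples
#' p <- networkPartition(rep(c("DMN", "CCN"), each = 3))
#' networkNames(p)
#' @export
networkPartition <- function(labels) {
  ids <- names(labels)
  if (is.null(ids))
    ids <- sprintf("IC%02d", seq_along(labels))
  f <- factor(as.character(labels))
  names(f) <- ids
  new("NetworkPartition", labels = f)
}

#' The shipped 53-component / 7-network template partition
#'
#' Loads the package's template assignment of 53 independent components to
#' seven functional networks (SCN 5, AUD 2, SMN 9, VSN 9, CCN 17, DMN 7,
#' CBN 4), mirroring the widely used NeuroMark fMRI 1.0 template layout.
#'
#' @return a [NetworkPartition-class] with 53 components and 7 networks.
#' @examples
#' p <- templatePartition()
#' table(partitionLabels(p))
#' @export
templatePartition <- function() {
  path <- system.file("extdata", "neuromark53_partition.tsv",
                      package = "fncBrainAge", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  networkPartition(stats::setNames(tab$network, tab$component))
}

#' @describeIn networkPartition factor of per-component network labels.
#' @param partition a [NetworkPartition-class].
#' @export
partitionLabels <- function(partition) partition@labels

#' @describeIn networkPartition distinct network names, in first-appearance
#'   order.
#' @export
networkNames <- function(partition)
  unique(as.character(partition@labels))

#' @describeIn networkPartition component ids belonging to one network.
#' @param network network label.
#' @export
networkComponents <- function(partition, network) {
  lab <- partition@labels
  if (!network %in% as.character(lab))
    stop("unknown network '", network, "'; valid labels: ",
         paste(unique(as.character(lab)), collapse = ", "))
  names(lab)[as.character(lab) == network]
}
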