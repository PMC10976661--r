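# Shared fixture builders for the suite.

# Random confusion counts with all four cells positive.
random_counts <- function() {
  confusion_counts(tp = sample(1:50, 1), fp = sample(1:50, 1),
                   tn = sample(1:50, 1), fn = sample(1:50, 1))
}

# A tiny three-topic corpus for ingest tests.
toy_corpus <- function() {
  tibble::tibble(
    id = sprintf("c%02d", 1:6),
    title = c("CT colonography accuracy", "MR angiography PAD",
              "Ultrasound DVT diagnosis", "PET adrenal tumors",
              "SPECT bone metastases", "Stents in PAD"),
    abstract = c("Accuracy of CT colonography for polyps.",
                 "CTA versus MRA for peripheral arterial disease.",
                 "Compression ultrasound for deep vein thrombosis.",
                 "FDG PET for adrenal lesions.",
                 "SPECT/CT detecting bone metastases.",
                 "Drug-eluting versus bare metal stents."),
    ref_type = "JOUR",
    pub_year = 2019:2024,
    topic = c("COLORECTAL", "PAD", "DVT", "PET", "SPECT", "STENT"),
    source_db = "pubmed"
  )
}

toy_picos <- function() {
  picos(
    population = "adults referred for diagnostic imaging",
    intervention = "index imaging test under evaluation",
    comparison = "reference standard or alternative imaging modality",
    outcomes = "diagnostic accuracy sensitivity specificity",
    study_design = "diagnostic accuracy study",
    topic_title = "imaging diagnostic accuracy"
  )
}
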