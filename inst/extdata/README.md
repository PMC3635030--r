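# Example tables

Consensus-feature and node-weight tables from a published 100-ROI
resting-state aging analysis, used as worked examples for the
feature-number mapping and the node-weight half-sum identity:

- `svm_consensus_features.csv` — 63 consensus features of a linear SVM
  young/old classifier (`feature_number`, `weight` magnitude).
- `svm_node_weights.csv` — the matching per-ROI node weights.
- `svr_consensus_features.csv` — 185 consensus features of a linear SVR
  age predictor (`feature_number`, `roi_i`, `roi_j`, `weight`).
- `svr_node_weights.csv` — the matching per-ROI node weights.

Printed feature weights are magnitudes; node weights for ROIs whose
incident features all share one sign equal exactly half the sum of the
incident feature weights.
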