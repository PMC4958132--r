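# Synthetic study fixture

All three data files here are **synthetic** (see the `_synthetic` suffix).
They are a stand-in for a 33-society hunter-gatherer religiosity dataset
whose per-society codings, calibrated supertree and divergence-date tables
are only distributed in journal supplementary material and are not
redistributed in this package.

What the fixture reproduces (from published aggregate statements only):

* `hg_religiosity_matrix_synthetic.csv` — 33 named societies; binary
  animism/afterlife/shamanism plus 4-state ancestor-worship and high-gods
  codings chosen so that the derived seven binary traits hit the published
  prevalences exactly (100/79/79/45/24/39/15 %), the active traits nest in
  their parent traits, and every per-society presence/absence fact stated
  in the article text holds (e.g. Slave: shamanism without afterlife;
  Hadza/Mbuti/Aka: neither).
* `hg_societies_tree_synthetic.nwk` — a fully resolved topology (plus
  `Outgroup`) matching the described continental structure: deep
  African/non-African split, Khoisan+Pygmy vs Hadza+Sandawe within Africa,
  Vedda as the deepest non-African lineage, then Andamanese and
  Australians, an East-Asian clade, and a Beringian/American clade
  (Eskimo-Aleut + Na-Dene sister to Amerind).
* `hg_age_constraints_synthetic.tsv` — two minimum-age date sets ("deep",
  molecular-scale; "shallow", minimum estimates) anchored at an
  out-of-Africa dispersal older than 60 kya.

Within-region topology details, branch lengths, and any coding not pinned
by the text are invented. `load_study_fixture()` verifies these files by
md5 before use.
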