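# podscape

Social-network and seascape-habitat analysis for photo-identified cetacean
populations.

Long-term photo-identification studies of social cetaceans — killer whales
in particular — ask whether a catalogue of individuals constitutes one
population or several socially and ecologically distinct subpopulations.
podscape implements the full analysis chain for that question, for
researchers working with encounter tables (date, position, identified
individuals) and bathymetry:

1. **Daily encounters** — consolidate raw sighting records into one record
   per group per day (first-sighting location, subset absorption, full
   provenance), and filter to fully identified groups and individuals seen
   at least 3 times.
2. **Association network** — pairwise simple ratio index under the gambit
   of the group: `SRI_ij = X_ij / (X_ij + Y_i + Y_j)`, the fraction of
   sampling units in which a pair was together out of those where either
   was seen.
3. **Community delineation** — average-linkage clustering on `1 − SRI`,
   tree fidelity by cophenetic correlation, and subpopulations at the
   dendrogram cut maximizing weighted Newman modularity
   `Q = Σ_c [ w_c/W − (s_c/2W)² ]`.
4. **Seascape covariates** — from an elevation raster: water depth,
   Euclidean distance to shore, *water* distance to the 200 m shelf-break
   isobath (shortest paths over water cells, respecting land barriers),
   shelf-width profiles, and 5-km survey-effort grids.
5. **MRQAP** — regression of the association matrix on habitat-similarity
   and geographic-proximity matrices, with significance from QAP
   permutations of the response.
6. **Habitat envelopes** — quantile envelopes (e.g., 90% of nearshore
   identifications within X km of shore), envelope-overlap zoning,
   mixed-association counts, and prey-composition tables.
7. **Simulator** — a seeded two-subpopulation fission-fusion system over a
   synthetic narrowing-shelf seascape with known ground truth, so the whole
   chain is verifiable end to end.

## Worked example

The numbered scripts under `analysis/` run the chain on the default
simulated study system and narrate what they find (outputs land under
`results/`):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_network.R
Rscript analysis/03_geospatial.R
Rscript analysis/04_mrqap.R
Rscript analysis/05_habitat.R
```

With the default seed this prints, among other things:

```
Simulated 167 individuals in 44 matrilines (91 inner / 76 outer).
Emitted 930 encounter records over 365 days; mean group size 10.2.
Consolidated 930 records into 812 daily encounters.
Network: 167 individuals retained, 0 excluded (<3 sightings).
Community delineation: 2 cluster(s), Q_max = 0.473 , CCC = 0.984
Adjusted Rand index vs simulated truth: 1.000
MRQAP on 167 individuals (27722 dyads): adj R^2 = 0.300, F = 2972.6
90% habitat envelopes: inner within 5.44 km of shore (coverage 0.900, n=5359);
  outer within 9.00 km of the shelf break (coverage 0.915, n=2924)
Mixed associations: 15 of 812 encounters (1.85%).
```

Reading these numbers: the clustering splits the 167 photo-identified
individuals into two clusters that match the simulated subpopulations
exactly (adjusted Rand index 1.0); the cophenetic correlation 0.98 says the
dendrogram represents the association matrix faithfully; Q_max ≈ 0.47 is
strong modular structure (a two-cluster partition is mathematically capped
at 0.5). The MRQAP confirms that habitat similarity predicts association
strength beyond geographic proximity, and the envelopes quantify each
cluster's habitat: 90% of nearshore-cluster identifications fall within
~5.4 km of shore, 90% of offshore-cluster identifications within ~9 km of
the shelf break. Mixed groups containing members of both clusters are rare
(<2% of encounters) and concentrate where the shelf approaches the shore.

The same chain runs on real data: read a sighting table with
`read_encounters()` (CSV or XLSX, with a column-mapping schema), project
coordinates with `ll_to_planar()`, and supply bathymetry as an ESRI ASCII
grid via `read_esri_ascii()`.

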