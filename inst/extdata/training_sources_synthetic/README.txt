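Synthetic training-pair source tables.

These files are constructed stand-ins that mirror the documented cardinality
and overlap structure of the operon-pair training sources for a bacterial
genome: a previous-study positive set (149 pairs), an experimentally
verified positive set (266 pairs), positives from six recently reported
operons (11 pairs, one of which repeats a previous-study pair), a previous
negative set (122 pairs, three of which were later verified as
co-transcribed and therefore reappear in the verified positive set), and 12
recent negatives. Gene identifiers are synthetic. Merging with
assemble_training_set() yields 425 known-operon pairs and 131 non-operon
pairs.
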