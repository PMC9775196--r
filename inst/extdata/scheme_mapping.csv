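# Default interscheme domain mapping. Anchor rows: verhaar 3 -> reactive,
# russom 6 -> specific, mechoa 1.3 -> narcotic. Remaining rows extend the
# anchors by each scheme's class semantics and are user-replaceable.
scheme,native_class,harmonized
verhaar,1,narcotic
verhaar,2,narcotic
verhaar,3,reactive
verhaar,4,specific
verhaar,5,unclassified_or_out_of_domain
russom,1,narcotic
russom,2,narcotic
russom,3,narcotic
russom,4,specific
russom,5,reactive
russom,6,specific
russom,7,specific
mechoa,1.1,narcotic
mechoa,1.2,narcotic
mechoa,1.3,narcotic
mechoa,1.4,narcotic
mechoa,2.1,reactive
mechoa,2.2,reactive
mechoa,3.1,reactive
mechoa,3.2,reactive
mechoa,3.3,reactive
mechoa,4.1,specific
mechoa,4.2,specific
mechoa,5.1,specific
mechoa,5.2,specific
mechoa,6.1,specific
mechoa,unclassified,unclassified_or_out_of_domain
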