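0c1b8f624b44e758666cedd78a5a1102  octane_properties.csv
d6355ae4462834919bb3db00777ac1f2  octane_structures.edges
233d7ef2269e822bc8b81aa55f2995b6  bhc_properties.csv
7b6fa9b389a05daac8043e52d82c9454  bhc_structures.edges
b5cf9e47077069876830679971ab418e  drug_properties.csv
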