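compound,class,rel_abundance
germacrene D,sesquiterpene_hydrocarbon,29.4
beta-caryophyllene,sesquiterpene_hydrocarbon,19.2
bicyclogermacrene,sesquiterpene_hydrocarbon,7.8
alpha-humulene,sesquiterpene_hydrocarbon,5.6
germacrene B,sesquiterpene_hydrocarbon,4.2
delta-cadinene,sesquiterpene_hydrocarbon,3.1
alpha-copaene,sesquiterpene_hydrocarbon,1.6
beta-elemene,sesquiterpene_hydrocarbon,1.1
sabinene,monoterpene_hydrocarbon,6.4
(E)-beta-ocimene,monoterpene_hydrocarbon,4.9
gamma-terpinene,monoterpene_hydrocarbon,2.9
alpha-pinene,monoterpene_hydrocarbon,2.2
myrcene,monoterpene_hydrocarbon,1.5
limonene,monoterpene_hydrocarbon,1.0
4-terpineol,oxygenated_monoterpene,3.1
linalool,oxygenated_monoterpene,0.8
caryophyllene oxide,oxygenated_sesquiterpene,2.9
spathulenol,oxygenated_sesquiterpene,1.8
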