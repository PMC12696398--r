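name,category,formula,molar_mass_g_per_mol,final_amount,final_amount_unit,stock_multiplier,solvent,storage,light_sensitive,notes
glycine,amino_acid,C2H5NO2,75.07,30,mg/l,1000,water,-20,FALSE,unverified against supplier sheet
L-arginine hydrochloride,amino_acid,C6H15ClN4O2,210.66,84,mg/l,1000,water,-20,FALSE,free-base Arg also usable; adjust molar mass
L-histidine hydrochloride monohydrate,amino_acid,C6H12ClN3O3,209.63,42,mg/l,1000,water,-20,FALSE,unverified against supplier sheet
L-lysine monohydrochloride,amino_acid,C6H15ClN2O2,182.65,146,mg/l,1000,water,-20,FALSE,100x working stock needs thorough mixing
L-methionine,amino_acid,C5H11NO2S,149.21,30,mg/l,1000,water,-20,FALSE,
L-cystine dihydrochloride,amino_acid,C6H14Cl2N2O4S2,313.22,63,mg/l,1000,1 M HCl,-20,FALSE,poorly water-soluble; dissolve in 1 M HCl
L-isoleucine,amino_acid,C6H13NO2,131.17,105,mg/l,100,water,-20,FALSE,
L-leucine,amino_acid,C6H13NO2,131.17,105,mg/l,100,water,-20,FALSE,
L-phenylalanine,amino_acid,C9H11NO2,165.19,66,mg/l,100,water,-20,FALSE,
L-serine,amino_acid,C3H7NO3,105.09,42,mg/l,100,water,-20,FALSE,
L-threonine,amino_acid,C4H9NO3,119.12,95,mg/l,100,water,-20,FALSE,
L-tryptophan,amino_acid,C11H12N2O2,204.23,16,mg/l,100,water,-20,FALSE,
L-tyrosine disodium salt dihydrate,amino_acid,C9H13NNa2O5,261.2,104,mg/l,100,water,-20,FALSE,unverified against supplier sheet
L-valine,amino_acid,C5H11NO2,117.15,94,mg/l,100,water,-20,FALSE,
choline chloride,vitamin,C5H14ClNO,139.62,4,mg/l,1000,water,-20,FALSE,
D-calcium pantothenate,vitamin,C18H32CaN2O10,476.53,4,mg/l,1000,water,-20,FALSE,
nicotinamide,vitamin,C6H6N2O,122.13,4,mg/l,1000,water,-20,FALSE,vitamin B3 amide
pyridoxine hydrochloride,vitamin,C8H12ClNO3,205.64,4,mg/l,1000,water,-20,TRUE,protect from light
thiamine hydrochloride,vitamin,C12H18Cl2N4OS,337.27,4,mg/l,1000,water,-20,TRUE,protect from light
i-inositol,vitamin,C6H12O6,180.16,7.2,mg/l,1000,water,-20,FALSE,
folic acid,vitamin,C19H19N7O6,441.4,4,mg/l,100,1 M NaOH,-20,TRUE,yellow in solution; added individually before filtration
riboflavin,vitamin,C17H20N4O6,376.36,0.4,mg/l,100,water,-20,TRUE,degrades in light; check color before use; added individually
iron(III) nitrate nonahydrate,inorganic_salt,FeH18N3O18,404,0.1,mg/l,2000,water,-20,FALSE,
calcium chloride dihydrate,inorganic_salt,CaCl2H4O2,147.02,264,mg/l,1000,water,-20,FALSE,unverified against supplier sheet
potassium chloride,inorganic_salt,KCl,74.55,400,mg/l,1000,water,-20,FALSE,stir with gentle heating (50 C); may recrystallize on cooling
magnesium sulfate,inorganic_salt,MgO4S,120.37,97.67,mg/l,200,water,-20,FALSE,may precipitate after thawing; warm and mix
sodium dihydrogen phosphate dihydrate,inorganic_salt,H6NaO6P,156.01,141,mg/l,200,water,-20,FALSE,may precipitate after thawing; warm and mix
sodium bicarbonate,buffer,CHNaO3,84.01,3700,mg/l,25,water,RT,FALSE,high-salt stock kept separate at RT
sodium chloride,inorganic_salt,NaCl,58.44,6400,mg/l,25,water,RT,FALSE,high-salt stock kept separate at RT
D-glucose,carbohydrate,C6H12O6,180.16,4500,mg/l,100,water,4,FALSE,high-glucose level; 100x stock factor is a derived default and overridable
FBS,supplement,,,10,%,10,,-20,FALSE,post-filtration supplement
dialyzed FBS,supplement,,,10,%,10,,-20,FALSE,post-filtration supplement for depletion media
L-glutamine,supplement,C5H10N2O3,146.15,2,mmol/l,100,water,-20,FALSE,unstable; supplement immediately before use
sodium pyruvate,supplement,C3H3NaO3,110.04,1,mmol/l,100,water,4,FALSE,post-filtration supplement
penicillin-streptomycin,supplement,,,1,%,100,,-20,FALSE,post-filtration supplement
L-proline,amino_acid,C5H9NO2,115.13,0.2,g/l,100,water,-20,FALSE,SILAC labeling media only; prevents Arg-to-Pro conversion
4-azido-L-homoalanine,label,C4H8N4O2,144.13,100,umol/l,1000,water,-20,TRUE,clickable Met analog (AHA); cytotoxic on prolonged exposure
L-tryptophan-13C11-15N2,label,[13C]11H12[15N]2O2,217.26,78.3430446,umol/l,100,water,-20,FALSE,heavy Trp for tracing; synthetic molar mass from label shift
L-arginine-13C6,label,[13C]6H14N4O2,180.22,398.7467958,umol/l,1000,water,-20,FALSE,intermediate SILAC Arg (Arg6); synthetic molar mass from label shift
L-arginine-13C6-15N4,label,[13C]6H14[15N]4O2,184.21,398.7467958,umol/l,1000,water,-20,FALSE,heavy SILAC Arg (Arg10); synthetic molar mass from label shift
L-lysine-D4,label,C6H11[2H]4ClN2O2,186.68,799.3430057,umol/l,1000,water,-20,FALSE,intermediate SILAC Lys (Lys4) as HCl salt; synthetic molar mass
L-lysine-13C6-15N2,label,[13C]6H15Cl[15N]2O2,190.66,799.3430057,umol/l,1000,water,-20,FALSE,heavy SILAC Lys (Lys8) as HCl salt; synthetic molar mass
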