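abbreviation	expansion
ID	intellectual disability
GDD	global developmental delay
FTT	failure to thrive
ASD	atrial septal defect
VSD	ventricular septal defect
HC	head circumference
OFC	occipitofrontal circumference
EEG	electroencephalogram
MRI	magnetic resonance imaging
PT	physical therapy
NICU	neonatal intensive care unit
GERD	gastroesophageal reflux disease
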