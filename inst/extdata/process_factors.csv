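symbol,process,name,units,low,mid,high
X1,ethanol extraction,Ethanol solution concentration for extraction,v/v %,80,85,90
X2,ethanol extraction,Extraction time,h,6.0,8.0,10.0
X3,ethanol extraction,Ethanol solution volume,mL,600,800,1000
X4,concentration,Volume of concentrated extract,mL,100,150,200
X5,water precipitation,Water added for water precipitation,mL,300,400,500
X6,column chromatography,Sampling flow rate,BV/h,1.0,1.5,2.0
X7,column chromatography,Washing flow rate,BV/h,1.0,1.5,2.0
X8,column chromatography,Water volume,BV,1.0,2.0,3.0
X9,column chromatography,Ethanol solution concentration for elution,v/v %,55,60,65
X10,column chromatography,Elution time,min,120,150,180
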