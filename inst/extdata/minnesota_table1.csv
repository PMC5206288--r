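phase,molecule,charged,model,value,error
water,cyclohexane,FALSE,experimental,1.2,NA
water,cyclohexane,FALSE,A,1.4,0.1
water,cyclohexane,FALSE,B,1.2,0.1
water,cyclohexane,FALSE,C,1.5,0.1
water,cyclohexane,FALSE,D,1.2,0.1
water,benzene,FALSE,experimental,-0.9,NA
water,benzene,FALSE,A,-0.5,0.1
water,benzene,FALSE,B,-0.6,0.1
water,benzene,FALSE,C,-0.2,0.1
water,benzene,FALSE,D,-0.6,0.1
water,aceticacid,FALSE,experimental,-6.7,NA
water,aceticacid,FALSE,A,-6.2,0.1
water,aceticacid,FALSE,B,-6.3,0.1
water,aceticacid,FALSE,C,-6.7,0.2
water,aceticacid,FALSE,D,-6.3,0.1
water,trimethylamine,FALSE,experimental,-3.2,NA
water,trimethylamine,FALSE,A,-2.6,0.1
water,trimethylamine,FALSE,B,-2.8,0.1
water,trimethylamine,FALSE,C,-2.1,0.1
water,trimethylamine,FALSE,D,-2.8,0.1
water,chlorobenzene,FALSE,experimental,-1.1,NA
water,chlorobenzene,FALSE,A,-0.2,0.1
water,chlorobenzene,FALSE,B,-0.5,0.1
water,chlorobenzene,FALSE,C,-0.1,0.1
water,chlorobenzene,FALSE,D,-0.5,0.1
water,methanol,FALSE,experimental,-5.1,NA
water,methanol,FALSE,A,-3.5,0.1
water,methanol,FALSE,B,-3.5,0.1
water,methanol,FALSE,C,-3.2,0.3
water,methanol,FALSE,D,-3.5,0.1
water,npropane,FALSE,experimental,2.0,NA
water,npropane,FALSE,A,2.6,0.1
water,npropane,FALSE,B,2.5,0.1
water,npropane,FALSE,C,2.6,0.1
water,npropane,FALSE,D,2.5,0.1
water,pyridine,FALSE,experimental,-4.7,NA
water,pyridine,FALSE,A,-3.3,0.1
water,pyridine,FALSE,B,-3.4,0.1
water,pyridine,FALSE,C,-3.3,0.1
water,pyridine,FALSE,D,-3.4,0.1
water,phenol,FALSE,experimental,-6.6,NA
water,phenol,FALSE,A,-5.7,0.1
water,phenol,FALSE,B,-5.9,0.1
water,phenol,FALSE,C,-4.5,0.6
water,phenol,FALSE,D,-5.9,0.1
water,acetone,FALSE,experimental,-3.9,NA
water,acetone,FALSE,A,-3.6,0.1
water,acetone,FALSE,B,-3.6,0.1
water,acetone,FALSE,C,-3.6,0.1
water,acetone,FALSE,D,-3.6,0.1
water,aniline,FALSE,experimental,-5.5,NA
water,aniline,FALSE,A,-5.2,0.1
water,aniline,FALSE,B,-5.4,0.1
water,aniline,FALSE,C,-4.8,0.4
water,aniline,FALSE,D,-5.4,0.1
water,trimethylammonium,TRUE,experimental,-61.4,NA
water,trimethylammonium,TRUE,A,-24.7,0.1
water,trimethylammonium,TRUE,B,-24.8,0.1
water,trimethylammonium,TRUE,C,-61.4,0.3
water,trimethylammonium,TRUE,D,-61.4,0.3
water,acetate,TRUE,experimental,-77.6,NA
water,acetate,TRUE,A,-74.8,0.1
water,acetate,TRUE,B,-74.9,0.2
water,acetate,TRUE,C,-81.1,0.3
water,acetate,TRUE,D,-81.1,0.3
cyclohexane,cyclohexane,FALSE,experimental,-4.4,NA
cyclohexane,cyclohexane,FALSE,A,-4.5,0.1
cyclohexane,cyclohexane,FALSE,B,-4.8,0.3
cyclohexane,cyclohexane,FALSE,C,-4.5,0.1
cyclohexane,benzene,FALSE,experimental,-4.2,NA
cyclohexane,benzene,FALSE,A,-3.0,0.1
cyclohexane,benzene,FALSE,B,-3.2,0.2
cyclohexane,benzene,FALSE,C,-4.0,0.1
cyclohexane,aceticacid,FALSE,experimental,-1.7,NA
cyclohexane,aceticacid,FALSE,A,-2.7,0.1
cyclohexane,aceticacid,FALSE,B,-2.8,0.2
cyclohexane,aceticacid,FALSE,C,-6.3,0.3
cyclohexane,trimethylamine,FALSE,experimental,-2.6,NA
cyclohexane,trimethylamine,FALSE,A,-3.1,0.1
cyclohexane,trimethylamine,FALSE,B,-3.2,0.1
cyclohexane,trimethylamine,FALSE,C,-4.2,0.1
cyclohexane,chlorobenzene,FALSE,experimental,-5.1,NA
cyclohexane,chlorobenzene,FALSE,A,-4.6,0.1
cyclohexane,chlorobenzene,FALSE,B,-4.7,0.2
cyclohexane,chlorobenzene,FALSE,C,-5.6,0.1
cyclohexane,methanol,FALSE,experimental,-1.3,NA
cyclohexane,methanol,FALSE,A,-0.6,0.1
cyclohexane,methanol,FALSE,B,-0.5,0.2
cyclohexane,methanol,FALSE,C,-3.1,0.1
cyclohexane,npropane,FALSE,experimental,-2.1,NA
cyclohexane,npropane,FALSE,A,-1.1,0.1
cyclohexane,npropane,FALSE,B,-1.1,0.1
cyclohexane,npropane,FALSE,C,-1.1,0.1
cyclohexane,pyridine,FALSE,experimental,-4.3,NA
cyclohexane,pyridine,FALSE,A,-4.2,0.1
cyclohexane,pyridine,FALSE,B,-4.4,0.3
cyclohexane,pyridine,FALSE,C,-6.0,0.1
cyclohexane,phenol,FALSE,experimental,-5.6,NA
cyclohexane,phenol,FALSE,A,-4.6,0.1
cyclohexane,phenol,FALSE,B,-4.6,0.1
cyclohexane,phenol,FALSE,C,-7.9,0.1
cyclohexane,acetone,FALSE,experimental,-2.7,NA
cyclohexane,acetone,FALSE,A,-2.0,0.1
cyclohexane,acetone,FALSE,B,-1.9,0.2
cyclohexane,acetone,FALSE,C,-4.2,0.1
cyclohexane,aniline,FALSE,experimental,-5.5,NA
cyclohexane,aniline,FALSE,A,-4.2,0.1
cyclohexane,aniline,FALSE,B,-4.9,0.2
cyclohexane,aniline,FALSE,C,-7.4,0.2
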