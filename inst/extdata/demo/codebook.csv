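level,concept_code,label,nhs_category,flag_ethnicity_race,flag_religion,flag_geography,flag_language,letter,high_level_sde,high_level_census2011,high_level_census2021,numeral,nhs_equivalent
CONCEPT,100000001,British,A,false,false,true,false,,,,,,
CONCEPT,100000002,English,A,false,false,true,false,,,,,,
CONCEPT,100000003,Scottish,A,false,false,true,false,,,,,,
CONCEPT,100000004,Welsh,A,false,false,true,false,,,,,,
CONCEPT,100000005,White - British,A,true,false,true,false,,,,,,
CONCEPT,100000011,Irish,B,false,false,true,false,,,,,,
CONCEPT,100000012,White - Irish,B,true,false,true,false,,,,,,
CONCEPT,100000021,Other White ethnic group,C,true,false,false,false,,,,,,
CONCEPT,100000022,Polish,C,false,false,true,false,,,,,,
CONCEPT,100000023,Greek,C,false,false,true,false,,,,,,
CONCEPT,100000024,Greek Orthodox,C,false,true,true,false,,,,,,
CONCEPT,100000025,Albanian,C,false,false,true,false,,,,,,
CONCEPT,100000026,Italian,C,false,false,true,false,,,,,,
CONCEPT,100000027,Bosnian,C,false,false,true,false,,,,,,
CONCEPT,100000028,White - Kosovan,C,true,false,true,false,,,,,,
CONCEPT,100000031,Gypsy,T,true,false,false,false,,,,,,
CONCEPT,100000032,Irish Traveller,T,true,false,true,false,,,,,,
CONCEPT,100000033,Traveller - Gypsy,T,true,false,false,false,,,,,,
CONCEPT,100000041,White and Black Caribbean,D,true,false,true,false,,,,,,
CONCEPT,100000051,White and Black African,E,true,false,true,false,,,,,,
CONCEPT,100000061,White and Asian,F,true,false,false,false,,,,,,
CONCEPT,100000071,Other Mixed background,G,true,false,false,false,,,,,,
CONCEPT,100000072,"Black - other, mixed",G,true,false,false,false,,,,,,
CONCEPT,100000081,Indian,H,false,false,true,false,,,,,,
CONCEPT,100000082,British Indian,H,false,false,true,false,,,,,,
CONCEPT,100000083,Punjabi speaking Indian,H,false,false,true,true,,,,,,
CONCEPT,100000084,Hindu Indian,H,false,true,true,false,,,,,,
CONCEPT,100000091,Pakistani,J,false,false,true,false,,,,,,
CONCEPT,100000092,Urdu speaking Pakistani,J,false,false,true,true,,,,,,
CONCEPT,100000101,Bangladeshi,K,false,false,true,false,,,,,,
CONCEPT,100000102,Bengali speaking Bangladeshi,K,false,false,true,true,,,,,,
CONCEPT,100000111,Other Asian background,L,true,false,false,false,,,,,,
CONCEPT,100000112,Sri Lankan,L,false,false,true,false,,,,,,
CONCEPT,100000113,Tamil speaking Asian,L,true,false,false,true,,,,,,
CONCEPT,100000114,Black East African Asian,L,true,false,true,false,,,,,,
CONCEPT,100000121,Chinese,R,false,false,true,false,,,,,,
CONCEPT,100000122,Cantonese speaking Chinese,R,false,false,true,true,,,,,,
CONCEPT,100000123,Mandarin speaking Chinese,R,false,false,true,true,,,,,,
CONCEPT,100000131,Caribbean,M,false,false,true,false,,,,,,
CONCEPT,100000132,Black Caribbean,M,true,false,true,false,,,,,,
CONCEPT,100000133,Black West Indian,M,true,false,true,false,,,,,,
CONCEPT,100000141,African,N,false,false,true,false,,,,,,
CONCEPT,100000142,Black African,N,true,false,true,false,,,,,,
CONCEPT,100000143,Somali,N,false,false,true,false,,,,,,
CONCEPT,100000144,Nigerian,N,false,false,true,false,,,,,,
CONCEPT,100000151,Other Black background,P,true,false,false,false,,,,,,
CONCEPT,100000152,Black British,P,true,false,true,false,,,,,,
CONCEPT,100000161,Any other ethnic group,S,true,false,false,false,,,,,,
CONCEPT,100000162,Vietnamese,S,false,false,true,false,,,,,,
CONCEPT,100000163,Filipino,S,false,false,true,false,,,,,,
CONCEPT,100000164,Japanese,S,false,false,true,false,,,,,,
CONCEPT,100000165,Moroccan,S,false,false,true,false,,,,,,
CONCEPT,100000166,Turkish,S,false,false,true,false,,,,,,
CONCEPT,100000167,Buddhist - other ethnic group,S,true,true,false,false,,,,,,
CONCEPT,100000171,Arab,W,true,false,false,false,,,,,,
CONCEPT,100000172,Arabic speaking - Arab,W,true,false,false,true,,,,,,
CONCEPT,100000173,Iraqi Arab,W,true,false,true,false,,,,,,
CONCEPT,100000181,Not stated,Z,false,false,false,false,,,,,,
CONCEPT,100000182,Ethnicity not stated,Z,false,false,false,false,,,,,,
NHS,,British,,,,,,A,White,White,White,,
NHS,,Irish,,,,,,B,White,White,White,,
NHS,,Any other White background,,,,,,C,White,White,White,,
NHS,,Gypsy or Irish Traveller,,,,,,T,Other Ethnic Groups,White,White,,
NHS,,White and Black Caribbean,,,,,,D,Mixed,Mixed,Mixed,,
NHS,,White and Black African,,,,,,E,Mixed,Mixed,Mixed,,
NHS,,White and Asian,,,,,,F,Mixed,Mixed,Mixed,,
NHS,,Any other Mixed background,,,,,,G,Mixed,Mixed,Mixed,,
NHS,,Indian,,,,,,H,Asian/Asian British,Asian/Asian British,Asian/Asian British,,
NHS,,Pakistani,,,,,,J,Asian/Asian British,Asian/Asian British,Asian/Asian British,,
NHS,,Bangladeshi,,,,,,K,Asian/Asian British,Asian/Asian British,Asian/Asian British,,
NHS,,Any other Asian background,,,,,,L,Asian/Asian British,Asian/Asian British,Asian/Asian British,,
NHS,,Chinese,,,,,,R,Other Ethnic Groups,Asian/Asian British,Asian/Asian British,,
NHS,,Caribbean,,,,,,M,Black/African/Caribbean/Black British,Black/African/Caribbean/Black British,Black/African/Caribbean/Black British,,
NHS,,African,,,,,,N,Black/African/Caribbean/Black British,Black/African/Caribbean/Black British,Black/African/Caribbean/Black British,,
NHS,,Any other Black background,,,,,,P,Black/African/Caribbean/Black British,Black/African/Caribbean/Black British,Black/African/Caribbean/Black British,,
NHS,,Any other ethnic group,,,,,,S,Other Ethnic Groups,Other Ethnic Groups,Other Ethnic Groups,,
NHS,,Arab,,,,,,W,Other Ethnic Groups,Other Ethnic Groups,Other Ethnic Groups,,
NHS,,Not stated,,,,,,Z,Unknown,Unknown,Unknown,,
NHS,,Not known (prior 2013),,,,,,X,Unknown,Unknown,Unknown,,
NHS,,Not known (2013 onwards),,,,,,99,Unknown,Unknown,Unknown,,
LEGACY,,,,,,,,,,,,0,WHITE_UNSPECIFIED
LEGACY,,,,,,,,,,,,1,M
LEGACY,,,,,,,,,,,,2,N
LEGACY,,,,,,,,,,,,3,P
LEGACY,,,,,,,,,,,,4,H
LEGACY,,,,,,,,,,,,5,J
LEGACY,,,,,,,,,,,,6,K
LEGACY,,,,,,,,,,,,7,R
LEGACY,,,,,,,,,,,,8,S
LEGACY,,,,,,,,,,,,9,Z
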